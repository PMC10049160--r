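#' Specification for a synthetic landscape
#'
#' Defines a reproducible synthetic study system: a multi-date 7-class
#' land-use map whose transitions are logistic functions of spatially
#' autocorrelated drivers, evolved under a per-step demand. The seed fully
#' determines every output, and the generator returns the exact per-cell
#' transition probabilities it used, so downstream estimators can be
#' scored against ground truth.
#'
#' Transition rules are given as a list of lists with elements `from`,
#' `to` (class codes), `intercept`, `coefs` (named numeric, one entry per
#' driver) and `demand` (cells converted per step).
#'
#' @param nrow,ncol Grid shape in cells.
#' @param cell_size Cell edge in meters (default 30, matching common
#'   national land-cover products).
#' @param n_classes Number of classes (default 7).
#' @param drivers Character vector of smooth-field driver names; a
#'   `dist_city` Euclidean-distance layer is always added.
#' @param correlation_length Gaussian smoothing length of the random
#'   fields, in cells.
#' @param transitions List of transition rules (see Details); by default
#'   [default_transitions()] with demands scaled to 4% (construction)
#'   and 2% (afforestation) of the grid per step.
#' @param seed Integer seed; determines all outputs.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nrow = 120, ncol = 120, cell_size = 30,
                           n_classes = 7,
                           drivers = c("terrain", "moisture", "access"),
                           correlation_length = 8,
                           transitions = NULL,
                           seed = 1L) {
  if (nrow < 2 || ncol < 2) stop("degenerate grid shape")
  if (is.null(transitions))
    transitions <- default_transitions(
      demand_construction = max(1, round(nrow * ncol / 25)),
      demand_forest = max(1, round(nrow * ncol / 50)))
  for (tr in transitions) {
    if (!all(is.finite(c(tr$intercept, tr$coefs))))
      stop("logit coefficients must be finite")
    if (tr$demand < 0 || tr$demand > nrow * ncol)
      stop("demand must be non-negative and at most the cell count")
  }
  structure(list(nrow = nrow, ncol = ncol, cell_size = cell_size,
                 n_classes = n_classes, drivers = drivers,
                 correlation_length = correlation_length,
                 transitions = transitions, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default synthetic transition rules
#'
#' Urbanisation of farmland and grassland driven by city proximity and
#' terrain, plus afforestation of grassland on moist terrain — the kinds
#' of conversions a basin-scale simulation must recover.
#'
#' @param demand_construction,demand_forest Cells converted per step.
#' @return List of transition rules for [synthetic_spec()].
#' @export
default_transitions <- function(demand_construction = 400,
                                demand_forest = 200) {
  list(
    list(from = 1L, to = 6L, intercept = -1.0,
         coefs = c(terrain = -1.5, moisture = 0, access = 1.0,
                   dist_city = -2.5),
         demand = demand_construction),
    list(from = 3L, to = 6L, intercept = -1.5,
         coefs = c(terrain = -1.0, moisture = 0, access = 1.0,
                   dist_city = -2.0),
         demand = round(demand_construction / 4)),
    list(from = 3L, to = 2L, intercept = -1.0,
         coefs = c(terrain = 1.0, moisture = 1.5, access = -0.5,
                   dist_city = 0.5),
         demand = demand_forest)
  )
}

# separable Gaussian smoothing with reflected edges
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  pad_smooth <- function(x) { # smooth each column of x, reflected edges
    n <- nrow(x)
    top <- pmin(pmax(rev(seq_len(half)) + 1L, 1L), n)
    bot <- pmin(pmax(n - seq_len(half), 1L), n)
    xp <- rbind(x[top, , drop = FALSE], x, x[bot, , drop = FALSE])
    out <- apply(xp, 2L, function(col) stats::filter(col, k, sides = 2))
    out[(half + 1):(half + n), , drop = FALSE]
  }
  sm <- pad_smooth(m)
  t(pad_smooth(t(sm)))
}

#' Generate a driver stack for a synthetic landscape
#'
#' Smooth random fields (white noise convolved with a Gaussian kernel of
#' the spec's correlation length) standardized to zero mean and unit
#' variance, plus a `dist_city` layer holding the standardized Euclidean
#' distance from each cell center to a seeded city point.
#'
#' @param spec A [synthetic_spec()].
#' @return A named list of numeric matrices (class `driver_stack`), with
#'   attributes `city` (row, col of the seeded city) and `cell_size`.
#' @export
make_drivers <- function(spec) {
  set.seed(spec$seed)
  nr <- spec$nrow; nc <- spec$ncol
  out <- list()
  for (nm in spec$drivers) {
    f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                         spec$correlation_length)
    out[[nm]] <- (f - mean(f)) / stats::sd(f)
  }
  city <- c(sample.int(nr, 1L), sample.int(nc, 1L))
  d <- sqrt(outer((seq_len(nr) - city[1])^2, (seq_len(nc) - city[2])^2, "+"))
  out[["dist_city"]] <- (d - mean(d)) / stats::sd(d)
  structure(out, class = "driver_stack", city = city,
            cell_size = spec$cell_size)
}

# initial map: spatially coherent classes from a smooth field + city patch
initial_landscape <- function(spec, drivers) {
  nr <- spec$nrow; nc <- spec$ncol
  base <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                          spec$correlation_length)
  q <- stats::quantile(base, c(0.45, 0.75, 0.9, 0.94, 0.97))
  codes <- matrix(1L, nr, nc)                  # farmland default
  codes[base > q[1]] <- 2L                     # forests
  codes[base > q[2]] <- 3L                     # grassland
  codes[base > q[3]] <- 4L                     # wetland
  codes[base > q[4]] <- 5L                     # waters
  codes[base > q[5]] <- 7L                     # unused
  city <- attr(drivers, "city")
  rr <- pmax(1L, city[1] - 3L):pmin(nr, city[1] + 3L)
  cc <- pmax(1L, city[2] - 3L):pmin(nc, city[2] + 3L)
  codes[rr, cc] <- 6L                          # construction seed
  landuse_grid(codes, cell_size = spec$cell_size)
}

#' Evolve a synthetic landscape with known transition probabilities
#'
#' At each step every transition rule converts `demand` cells of its
#' source class, drawn without replacement with probability proportional
#' to the logistic transition probability
#' `plogis(intercept + coefs . drivers)`. The exact probabilities used
#' are returned so estimated development-probability surfaces can be
#' scored against the truth.
#'
#' @param spec A [synthetic_spec()].
#' @param steps Number of transition steps (>= 1).
#' @return List with `maps` (list of `steps + 1` [landuse_grid()]s),
#'   `drivers` (the [make_drivers()] stack) and `truth` — per step, per
#'   rule, a list with the rule and its per-cell probability matrix
#'   (`NA` on cells not of the source class).
#' @export
evolve_landscape <- function(spec, steps = 1L) {
  if (steps < 1) stop("`steps` must be >= 1")
  drivers <- make_drivers(spec)   # seeds the stream
  start <- initial_landscape(spec, drivers)
  maps <- list(start)
  truth <- vector("list", steps)
  nr <- spec$nrow; nc <- spec$ncol
  for (s in seq_len(steps)) {
    cur <- maps[[s]]$codes
    nxt <- cur
    converted <- matrix(FALSE, nr, nc)
    truth[[s]] <- vector("list", length(spec$transitions))
    for (k in seq_along(spec$transitions)) {
      tr <- spec$transitions[[k]]
      eta <- matrix(tr$intercept, nr, nc)
      for (nm in names(tr$coefs))
        eta <- eta + tr$coefs[[nm]] * drivers[[nm]]
      p <- stats::plogis(eta)
      eligible <- which(cur == tr$from & !converted & !is.na(cur))
      p_true <- matrix(NA_real_, nr, nc)
      p_true[eligible] <- p[eligible]
      truth[[s]][[k]] <- list(from = tr$from, to = tr$to, p = p_true)
      if (tr$demand == 0 || length(eligible) == 0) next
      if (tr$demand > length(eligible))
        stop("demand for rule ", k, " exceeds available cells at step ", s)
      pick <- sample(eligible, tr$demand, prob = p[eligible])
      nxt[pick] <- tr$to
      converted[pick] <- TRUE
    }
    maps[[s + 1]] <- landuse_grid(nxt, cell_size = spec$cell_size,
                                  origin = maps[[s]]$origin)
  }
  list(maps = maps, drivers = drivers, truth = truth)
}

#' Geometric series fixture
#'
#' `start * ratio^(k-1)` for `k = 1..n`; the canonical exactly-fittable
#' input for the GM(1,1) gray model.
#'
#' @param start First value (> 0).
#' @param ratio Common ratio (> 0).
#' @param n Length (>= 4 for downstream gray fitting).
#' @return Numeric vector of length `n`.
#' @export
make_series <- function(start, ratio, n) {
  if (start <= 0 || ratio <= 0) stop("`start` and `ratio` must be positive")
  if (n < 1) stop("`n` must be positive")
  start * ratio^(seq_len(n) - 1)
}
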