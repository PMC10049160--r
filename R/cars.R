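#' Boolean land-use transition matrix
#'
#' `allowed[from, to]` gates conversions during allocation. Persistence
#' (the diagonal) is always allowed and is forced to `TRUE`.
#'
#' @param allowed Optional 7 x 7 logical matrix; default all allowed.
#' @param forbid Optional two-column matrix / data frame of (from, to)
#'   code pairs to forbid.
#' @return 7 x 7 logical matrix with class-name dimnames.
#' @export
transition_rules <- function(allowed = NULL, forbid = NULL) {
  k <- length(lu_legend())
  if (is.null(allowed)) allowed <- matrix(TRUE, k, k)
  if (!is.null(forbid)) {
    forbid <- as.matrix(forbid)
    allowed[forbid] <- FALSE
  }
  diag(allowed) <- TRUE
  dimnames(allowed) <- list(from = lu_classes(), to = lu_classes())
  allowed
}

#' Parameters of the patch-seeding cellular automaton
#'
#' @param neighborhood_radius Moore-window radius in cells (default 1).
#' @param neighborhood_weights Per-class weights in `[0, 1]` scaling the
#'   neighborhood effect (default 1 for all classes).
#' @param patch_seed_prob Per-class probability `mu` that a cell with no
#'   neighborhood support may nucleate a new patch in a sweep
#'   (default 0.02).
#' @param decay Threshold-decay factor `delta` in (0, 1) shrinking the
#'   seeding threshold each sweep (default 0.9).
#' @param inertia_step Adaptive-inertia adjustment `epsilon`: inertia of
#'   an under-allocated class is multiplied by `1 + epsilon` each sweep,
#'   of an over-allocated class divided (default 0.1).
#' @param max_iter Maximum sweeps (default 200).
#' @param tolerance_cells Absolute demand tolerance in cells; the
#'   effective per-class tolerance is
#'   `max(tolerance_cells, tolerance_frac * demand)`.
#' @param tolerance_frac Relative demand tolerance (default 0.001).
#' @param seed Integer RNG seed; identical inputs and seed give an
#'   identical output map.
#' @return Object of class `cars_params`.
#' @export
cars_params <- function(neighborhood_radius = 1L,
                        neighborhood_weights = rep(1, 7),
                        patch_seed_prob = rep(0.02, 7),
                        decay = 0.9,
                        inertia_step = 0.1,
                        max_iter = 200L,
                        tolerance_cells = 1,
                        tolerance_frac = 0.001,
                        seed = 1L) {
  if (length(patch_seed_prob) == 1L) patch_seed_prob <- rep(patch_seed_prob, 7)
  if (length(neighborhood_weights) == 1L)
    neighborhood_weights <- rep(neighborhood_weights, 7)
  stopifnot(all(neighborhood_weights >= 0 & neighborhood_weights <= 1),
            all(patch_seed_prob >= 0 & patch_seed_prob <= 1),
            decay > 0, decay < 1, tolerance_cells >= 0)
  structure(list(neighborhood_radius = as.integer(neighborhood_radius),
                 neighborhood_weights = neighborhood_weights,
                 patch_seed_prob = patch_seed_prob,
                 decay = decay, inertia_step = inertia_step,
                 max_iter = as.integer(max_iter),
                 tolerance_cells = tolerance_cells,
                 tolerance_frac = tolerance_frac,
                 seed = as.integer(seed)),
            class = "cars_params")
}

# box-sum of a 0/1 matrix over a (2r+1)^2 window via shifted adds
window_sum <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  # cumulative-sum (summed-area table) approach, O(n)
  pad <- matrix(0, nr + 2 * r + 1, nc + 2 * r + 1)
  pad[(r + 2):(r + 1 + nr), (r + 2):(r + 1 + nc)] <- m
  sat <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed SAT
  # sat is (nc+2r+1) x (nr+2r+1): sat[j, i] = sum pad[1:i, 1:j]
  i1 <- 1:nr; i2 <- i1 + 2 * r + 1
  j1 <- 1:nc; j2 <- j1 + 2 * r + 1
  t(sat[j2, i2] - sat[j1, i2] - sat[j2, i1] + sat[j1, i1])
}

#' Neighborhood effect of a class
#'
#' Per cell, the fraction of class-`class_i` cells in the surrounding
#' `(2r+1)^2` Moore window (center excluded), scaled by the class
#' neighborhood weight. Range `[0, weight]`.
#'
#' @param grid A [landuse_grid()].
#' @param class_i Class code.
#' @param params A [cars_params()].
#' @return Numeric matrix of the grid's shape.
#' @export
neighborhood_effect <- function(grid, class_i, params = cars_params()) {
  w <- params$neighborhood_weights[class_i]
  if (w == 0) return(matrix(0, nrow(grid$codes), ncol(grid$codes)))
  r <- params$neighborhood_radius
  ind <- (!is.na(grid$codes) & grid$codes == class_i) * 1
  cnt <- window_sum(ind, r) - ind
  w * cnt / ((2 * r + 1)^2 - 1)
}

#' Demand-constrained patch-generating allocation
#'
#' Evolves the base map until every class's cell count is within
#' tolerance of its demand, or `max_iter` sweeps elapse. Each sweep:
#'
#' 1. Classes above demand are donors, classes below are receivers; a
#'    cell may leave its class only while that class is over-allocated
#'    and may join a class only while it is under-allocated, so the
#'    per-class absolute demand gap is non-increasing.
#' 2. The score for converting cell x (class f) to receiver class j is
#'    `P_j(x) * neighborhood_j(x) * inertia_j * multiplier[f, j]`, zeroed
#'    where the transition matrix forbids f -> j or x is restricted.
#'    Cells with zero neighborhood support can score only by random
#'    patch seeding: with probability `mu_j` and `P_j(x)` above a
#'    threshold that shrinks by `decay` each sweep, the development
#'    probability itself is used in place of the neighborhood term.
#' 3. Each donor cell draws a candidate receiver by roulette wheel over
#'    its scores; proposals are accepted in decreasing score order while
#'    donor surplus and receiver need remain, optionally capped by
#'    `max_loss` conversions away from each class.
#'
#' Nodata and restricted cells never move; the total mapped cell count
#' is conserved by construction.
#'
#' @param base Base-year [landuse_grid()].
#' @param probs `development_probability` surfaces from
#'   [fit_development()] (a named list of matrices).
#' @param demand Target per-class areas in ha (`demand_vector`) or an
#'   integer vector of target cells (`cells = TRUE`).
#' @param tmatrix 7 x 7 logical [transition_rules()] matrix.
#' @param restricted Logical matrix of frozen cells (default none).
#' @param multipliers 7 x 7 scenario score multipliers (default 1).
#' @param params A [cars_params()].
#' @param max_loss Optional per-class cap on cells converting away
#'   (development-intensity cap); `Inf` = uncapped.
#' @param cells If `TRUE`, `demand` is already in cells.
#' @return List with `map` (the allocated [landuse_grid()]), `log`
#'   (data frame: iteration, class, gap, inertia), `converged`, and
#'   `unmet` (named residual gaps in cells).
#' @export
allocate <- function(base, probs, demand, tmatrix = transition_rules(),
                     restricted = NULL, multipliers = NULL,
                     params = cars_params(), max_loss = NULL,
                     cells = FALSE) {
  k <- length(base$legend)
  codes <- base$codes
  nr <- nrow(codes); nc <- ncol(codes)
  if (is.null(restricted)) restricted <- matrix(FALSE, nr, nc)
  if (is.null(multipliers)) multipliers <- matrix(1, k, k)
  if (is.null(max_loss)) max_loss <- rep(Inf, k)
  target <- if (cells) as.numeric(demand) else
    as.numeric(demand_to_cells(demand, base))
  counts <- tabulate(codes[!is.na(codes)], nbins = k)
  if (abs(sum(target) - sum(counts)) > 1)
    stop("demand total (", sum(target), " cells) does not match mapped area (",
         sum(counts), " cells)")
  tol <- pmax(params$tolerance_cells, params$tolerance_frac * target)
  set.seed(params$seed)
  inertia <- rep(1, k)
  threshold <- 1
  loss <- rep(0, k)
  movable <- !is.na(codes) & !restricted
  log_rows <- vector("list", params$max_iter)
  gap <- target - counts
  stalled <- 0L
  if (!is.null(names(probs)) && all(lu_classes() %in% names(probs)))
    probs <- probs[lu_classes()]
  for (iter in seq_len(params$max_iter)) {
    if (all(abs(gap) <= tol)) break
    receivers <- which(gap > tol)
    donors_cls <- which(gap < -tol & loss < max_loss[seq_len(k)])
    if (length(receivers) == 0 || length(donors_cls) == 0) break
    # adaptive inertia
    inertia[gap > 0] <- inertia[gap > 0] * (1 + params$inertia_step)
    inertia[gap < 0] <- inertia[gap < 0] / (1 + params$inertia_step)
    donor_cells <- which(movable & matrix(codes %in% donors_cls, nr, nc))
    if (length(donor_cells) == 0) break
    from_cls <- codes[donor_cells]
    scores <- matrix(0, length(donor_cells), k)
    for (j in receivers) {
      pj <- probs[[j]][donor_cells]
      pj[is.na(pj)] <- 0
      neigh <- neighborhood_effect(
        landuse_grid_unchecked(codes, base), j, params)[donor_cells]
      # random patch seeding where there is no neighborhood support
      zero_n <- neigh <= 0
      if (any(zero_n)) {
        seeded <- zero_n & stats::runif(length(neigh)) <
          params$patch_seed_prob[j] & pj > threshold
        neigh[zero_n] <- 0
        neigh[seeded] <- pj[seeded]
      }
      s <- pj * neigh * inertia[j] * multipliers[cbind(from_cls, j)]
      s[!tmatrix[cbind(from_cls, j)]] <- 0
      scores[, j] <- s
    }
    tot <- rowSums(scores)
    active <- which(tot > 0)
    if (length(active) == 0) {
      threshold <- threshold * params$decay
      log_rows[[iter]] <- sweep_log(iter, gap, inertia)
      stalled <- stalled + 1L
      if (stalled >= 25L) break   # no convertible cell in 25 sweeps
      next
    }
    # roulette-wheel draw of the candidate class per active donor cell
    u <- stats::runif(length(active)) * tot[active]
    cum <- t(apply(scores[active, , drop = FALSE], 1L, cumsum))
    choice <- max.col(cum >= u, ties.method = "first")
    score_at <- scores[cbind(active, choice)]
    # accept proposals in decreasing score order under both-side caps
    ord <- active[order(score_at, decreasing = TRUE)]
    choice <- choice[order(score_at, decreasing = TRUE)]
    need <- gap          # receiver need (>0) / donor surplus (<0), in cells
    for (idx in seq_along(ord)) {
      f <- from_cls[ord[idx]]
      j <- choice[idx]
      if (need[j] <= 0) next
      if (need[f] >= 0) next
      if (loss[f] >= max_loss[f]) next
      cell <- donor_cells[ord[idx]]
      codes[cell] <- j
      need[j] <- need[j] - 1
      need[f] <- need[f] + 1
      loss[f] <- loss[f] + 1
      if (all(need[receivers] <= 0)) break
    }
    converted_this_sweep <- sum(abs(need - gap)) / 2
    counts <- tabulate(codes[!is.na(codes)], nbins = k)
    gap <- target - counts
    stalled <- if (converted_this_sweep == 0) stalled + 1L else 0L
    if (stalled >= 25L) { log_rows[[iter]] <- sweep_log(iter, gap, inertia); break }
    threshold <- threshold * params$decay
    log_rows[[iter]] <- sweep_log(iter, gap, inertia)
  }
  log_df <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
  converged <- all(abs(gap) <= tol)
  unmet <- stats::setNames(gap, lu_classes())
  if (!converged)
    warning("allocation did not meet demand for: ",
            paste(sprintf("%s (%+d cells)", lu_classes()[abs(gap) > tol],
                          as.integer(gap[abs(gap) > tol])), collapse = ", "))
  list(map = landuse_grid(codes, cell_size = base$cell_size,
                          origin = base$origin, legend = base$legend),
       log = log_df, converged = converged, unmet = unmet)
}

sweep_log <- function(iter, gap, inertia) {
  data.frame(iteration = iter, class = lu_classes(),
             gap = as.integer(gap), inertia = inertia, row.names = NULL)
}

# cheap internal wrapper when codes are already validated
landuse_grid_unchecked <- function(codes, template) {
  g <- template
  g$codes <- codes
  g
}
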