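#' Sample expansion and non-expansion cells for one class
#'
#' The land-expansion analysis samples, for class `class_i`, the cells
#' newly converted to that class between two dates (positives) and a
#' uniform sample of unconverted cells (negatives), balanced 1:1 by
#' default.
#'
#' @param grid_t0,grid_t1 Aligned [landuse_grid()]s at the two dates.
#' @param class_i Class code whose expansion is analysed.
#' @param balance Negatives per positive (default 1).
#' @param max_positives Optional cap on positives (downsampled).
#' @param seed Integer seed for the negative (and any positive) sampling.
#' @return Data frame with `cell` (linear index), `row`, `col`, `label`
#'   (1 expansion / 0 not); zero rows with attribute
#'   `no_expansion = TRUE` when the class gained no cells.
#' @export
sample_expansion <- function(grid_t0, grid_t1, class_i, balance = 1,
                             max_positives = Inf, seed = 1L) {
  check_aligned(grid_t0, grid_t1)
  a <- grid_t0$codes; b <- grid_t1$codes
  mapped <- !is.na(a) & !is.na(b)
  pos <- which(mapped & b == class_i & a != class_i)
  if (length(pos) == 0) {
    out <- data.frame(cell = integer(), row = integer(), col = integer(),
                      label = integer())
    attr(out, "no_expansion") <- TRUE
    return(out)
  }
  set.seed(seed)
  if (length(pos) > max_positives) pos <- sample(pos, max_positives)
  negpool <- which(mapped & !(b == class_i & a != class_i))
  n_neg <- min(length(negpool), round(balance * length(pos)))
  neg <- sample(negpool, n_neg)
  cells <- c(pos, neg)
  out <- data.frame(cell = cells,
                    row = ((cells - 1L) %% nrow(a)) + 1L,
                    col = ((cells - 1L) %/% nrow(a)) + 1L,
                    label = rep(c(1L, 0L), c(length(pos), n_neg)))
  attr(out, "no_expansion") <- FALSE
  out
}

#' Fit development-probability surfaces with a random-forest ensemble
#'
#' For each requested class, trains a binary probability forest
#' (expansion vs not, one model per class) on the sampled cells' driver
#' values and predicts the expansion probability at every mapped cell.
#' Classes with no observed expansion get an all-zero surface.
#'
#' @param grid_t0,grid_t1 Aligned historical [landuse_grid()]s.
#' @param drivers A named list of driver matrices ([make_drivers()] stack
#'   or equivalent), aligned with the grids.
#' @param classes Class codes to model (default all in the legend).
#' @param num_trees Trees per forest (default 100).
#' @param balance Negative:positive sampling ratio (default 1).
#' @param max_positives Cap on positives per class.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return Object of class `development_probability`: a named list of
#'   probability matrices in `[0, 1]` (one per class, `NA` where the
#'   grid is nodata), with attribute `importance` (per-class named
#'   driver-importance vectors).
#' @export
fit_development <- function(grid_t0, grid_t1, drivers,
                            classes = unname(grid_t0$legend),
                            num_trees = 100, balance = 1,
                            max_positives = 5000, seed = 1L) {
  dnames <- names(drivers)[!names(drivers) %in%
                             c("centers_x", "centers_y", "cell_area_ha")]
  X_all <- as.data.frame(lapply(drivers[dnames], as.vector))
  mapped <- which(!is.na(grid_t0$codes))
  surfaces <- list()
  importance <- list()
  for (cl in classes) {
    key <- names(grid_t0$legend)[match(cl, grid_t0$legend)]
    samp <- sample_expansion(grid_t0, grid_t1, cl, balance = balance,
                             max_positives = max_positives,
                             seed = seed + cl)
    m <- matrix(NA_real_, nrow(grid_t0$codes), ncol(grid_t0$codes))
    if (isTRUE(attr(samp, "no_expansion")) ||
        length(unique(samp$label)) < 2L || nrow(samp) < 4L) {
      m[mapped] <- 0
      surfaces[[key]] <- m
      importance[[key]] <- stats::setNames(rep(0, length(dnames)), dnames)
      next
    }
    df <- X_all[samp$cell, , drop = FALSE]
    df$label <- factor(samp$label, levels = c(0L, 1L))
    fit <- ranger::ranger(label ~ ., data = df, num.trees = num_trees,
                          probability = TRUE, seed = seed + cl,
                          num.threads = 1L, importance = "impurity")
    pred <- stats::predict(fit, X_all[mapped, , drop = FALSE],
                           num.threads = 1L)$predictions
    m[mapped] <- pred[, "1"]
    surfaces[[key]] <- m
    importance[[key]] <- fit$variable.importance
  }
  structure(surfaces, class = "development_probability",
            importance = importance)
}

#' Write development-probability surfaces to ESRI ASCII grids
#'
#' One file per class, named `<prefix>_<class>.asc`.
#'
#' @param probs A `development_probability` object.
#' @param prefix Path prefix for the output files.
#' @param grid The associated [landuse_grid()] (georeferencing).
#' @return Character vector of written paths, invisibly.
#' @export
write_development <- function(probs, prefix, grid) {
  paths <- character(0)
  for (nm in names(probs)) {
    p <- paste0(prefix, "_", nm, ".asc")
    write_asc(probs[[nm]], p, cell_size = grid$cell_size,
              origin = grid$origin)
    paths <- c(paths, p)
  }
  invisible(paths)
}
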