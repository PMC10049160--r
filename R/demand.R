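#' Fit a Markov transition model from a cross-tabulation
#'
#' Each row of the transition-probability matrix is the corresponding
#' crosstab row divided by its sum; classes with no area at the from-date
#' get an identity row (they persist). Applying the fitted matrix to the
#' from-date areas reproduces the to-date areas exactly.
#'
#' @param crosstab K x K area matrix from [crosstab()].
#' @param interval Length of the observed interval in years.
#' @return Object of class `markov_model`: list with `P` (row-stochastic
#'   matrix) and `interval`.
#' @export
fit_markov <- function(crosstab, interval = 1) {
  if (all(crosstab == 0)) stop("all-zero crosstab")
  if (any(crosstab < 0)) stop("crosstab entries must be non-negative")
  if (is.null(dimnames(crosstab)) && nrow(crosstab) == length(lu_legend()))
    dimnames(crosstab) <- list(from = lu_classes(), to = lu_classes())
  rs <- rowSums(crosstab)
  P <- crosstab / ifelse(rs > 0, rs, 1)
  empty <- rs == 0
  if (any(empty)) {
    P[empty, ] <- 0
    P[cbind(which(empty), which(empty))] <- 1
  }
  structure(list(P = P, interval = interval), class = "markov_model")
}

#' Project class areas with a Markov model
#'
#' Computes `areas %*% P^n`. Row-stochasticity conserves the total area.
#'
#' @param model A [fit_markov()] model.
#' @param areas Named numeric vector of per-class areas (ha), or an
#'   [class_areas()] data frame (its `area_ha` column is used).
#' @param n_intervals Number of model intervals to project (>= 1).
#' @return Named numeric vector of projected areas (ha), class
#'   `demand_vector`.
#' @export
project_markov <- function(model, areas, n_intervals = 1L) {
  if (n_intervals < 1) stop("`n_intervals` must be >= 1")
  a <- as_area_vector(areas, rownames(model$P))
  Pn <- diag(nrow(model$P))
  for (i in seq_len(n_intervals)) Pn <- Pn %*% model$P
  out <- drop(a %*% Pn)
  names(out) <- colnames(model$P)
  structure(out, class = "demand_vector")
}

as_area_vector <- function(areas, class_names = lu_classes()) {
  if (is.data.frame(areas)) {
    v <- areas$area_ha
    names(v) <- if (!is.null(areas$class)) areas$class else class_names
  } else v <- areas
  if (!is.null(class_names) && !is.null(names(v))) v <- v[class_names]
  unclass(v)
}

#' Linear-trend demand projection
#'
#' Per-class ordinary least-squares line of area against year, evaluated
#' at the target year. Negative extrapolations are clamped to zero and
#' the shortfall is redistributed proportionally over the positive
#' classes so the total mapped area is conserved.
#'
#' @param areas_by_date Data frame with columns `year`, `class`,
#'   `area_ha`, covering at least three dates.
#' @param target_year Year to extrapolate to.
#' @return Named numeric vector of areas (ha), class `demand_vector`.
#' @export
project_linear <- function(areas_by_date, target_year) {
  years <- sort(unique(areas_by_date$year))
  if (length(years) < 3) stop("at least three dates are required")
  classes <- unique(areas_by_date$class)
  pred <- vapply(classes, function(cl) {
    d <- areas_by_date[areas_by_date$class == cl, ]
    fit <- stats::lm(area_ha ~ year, data = d)
    unname(stats::predict(fit, data.frame(year = target_year)))
  }, numeric(1))
  neg <- pred < 0
  if (any(neg)) {
    # clamp and take the shortfall proportionally from positive classes,
    # conserving the projected total
    shortfall <- -sum(pred[neg])
    pred[neg] <- 0
    pos <- pred > 0
    pred[pos] <- pred[pos] - shortfall * pred[pos] / sum(pred[pos])
  }
  structure(pred, names = classes, class = "demand_vector")
}

#' Blend Markov and linear demand projections
#'
#' The natural-evolution baseline demand. The default weight 1 uses the
#' Markov projection alone; the linear projection is reported alongside
#' as a cross-check and can be blended in.
#'
#' @param markov_demand,linear_demand `demand_vector`s over the same
#'   classes.
#' @param weight_markov Blend weight in `[0, 1]` on the Markov component.
#' @return Blended `demand_vector`.
#' @export
blend_demand <- function(markov_demand, linear_demand, weight_markov = 1) {
  if (weight_markov < 0 || weight_markov > 1) stop("weight must be in [0,1]")
  out <- weight_markov * unclass(markov_demand) +
    (1 - weight_markov) * unclass(linear_demand)[names(markov_demand)]
  structure(out, class = "demand_vector")
}

#' Convert a demand vector in hectares to whole cells
#'
#' Largest-remainder rounding so the cell total equals the mapped cell
#' count exactly.
#'
#' @param demand Named areas in ha.
#' @param grid The base [landuse_grid()] (supplies cell area and total).
#' @return Named integer vector of target cell counts.
#' @export
demand_to_cells <- function(demand, grid) {
  total_cells <- sum(!is.na(grid$codes))
  raw <- unclass(demand) / cell_area_ha(grid)
  raw <- raw * total_cells / sum(raw)   # guard against input rounding
  fl <- floor(raw)
  rem <- total_cells - sum(fl)
  if (rem > 0) {
    order_frac <- order(raw - fl, decreasing = TRUE)
    fl[order_frac[seq_len(rem)]] <- fl[order_frac[seq_len(rem)]] + 1
  }
  structure(as.integer(fl), names = names(demand))
}
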