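#' Confusion matrix of two categorical maps
#'
#' Cellwise cross-tabulation of a reference map (rows) against a
#' simulated map (columns), excluding nodata.
#'
#' @param reference,simulated Aligned [landuse_grid()]s.
#' @return K x K count matrix with class-name dimnames (class
#'   `confusion_matrix`).
#' @export
confusion <- function(reference, simulated) {
  na_any <- check_aligned(reference, simulated, mask = "intersect")
  keep <- !na_any
  lv <- reference$legend
  m <- unclass(table(factor(reference$codes[keep], levels = lv),
                     factor(simulated$codes[keep], levels = lv)))
  dimnames(m) <- list(reference = names(lv), simulated = names(lv))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Overall accuracy
#'
#' Trace of the confusion matrix over its total.
#'
#' @param cm A count matrix (reference rows, simulated columns).
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa of a confusion matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' products of row and column marginals. A degenerate single-class
#' matrix has `p_e = 1`; kappa is then undefined and `NA` is returned
#' with a warning.
#'
#' @param cm A count matrix (reference rows, simulated columns).
#' @return Kappa coefficient, or `NA` if undefined.
#' @export
kappa_coefficient <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warning("chance agreement is 1 (single-class matrix); kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Figure of merit of a change simulation
#'
#' Computed over the union of observed and simulated change:
#' `FoM = B / (A + B + C + D)` where, cell by cell,
#' A = observed change simulated as persistence (misses),
#' B = observed change simulated as the correct new class (hits),
#' C = observed change simulated as change to a wrong class,
#' D = observed persistence simulated as change (false alarms).
#' Nodata cells are excluded from all four components. If no cell shows
#' observed or simulated change, the ratio is undefined and `NA` is
#' returned with a warning.
#'
#' @param reference_t0 Observed start map.
#' @param reference_t1 Observed end map.
#' @param simulated_t1 Simulated end map.
#' @return Fraction in `[0, 1]`, or `NA` if undefined.
#' @export
figure_of_merit <- function(reference_t0, reference_t1, simulated_t1) {
  na1 <- check_aligned(reference_t0, reference_t1)
  na2 <- check_aligned(reference_t0, simulated_t1)
  keep <- !(na1 | na2)
  o0 <- reference_t0$codes[keep]
  o1 <- reference_t1$codes[keep]
  s1 <- simulated_t1$codes[keep]
  obs_change <- o0 != o1
  sim_change <- o0 != s1
  A <- sum(obs_change & !sim_change)
  B <- sum(obs_change & sim_change & o1 == s1)
  C <- sum(obs_change & sim_change & o1 != s1)
  D <- sum(!obs_change & sim_change)
  denom <- A + B + C + D
  if (denom == 0) {
    warning("no observed or simulated change; figure of merit undefined")
    return(NA_real_)
  }
  B / denom
}
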