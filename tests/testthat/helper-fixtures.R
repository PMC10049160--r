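# Shared fixtures and brute-force oracles. Oracles enumerate definitions
# directly and stay independent of the implementation paths they check.

tiny_grid <- function(codes, nrow, ncol, cell_size = 100, origin = c(0, 0)) {
  landuse_grid(matrix(as.integer(codes), nrow, ncol), cell_size = cell_size,
               origin = origin)
}

rand_grid <- function(seed, nrow = 20, ncol = 20, cell_size = 30,
                      classes = 1:7, p_nodata = 0) {
  set.seed(seed)
  codes <- sample(classes, nrow * ncol, replace = TRUE)
  if (p_nodata > 0) codes[runif(nrow * ncol) < p_nodata] <- NA
  landuse_grid(matrix(as.integer(codes), nrow, ncol), cell_size = cell_size)
}

# per-class cell counts by direct enumeration
bf_class_counts <- function(grid) {
  vapply(unname(lu_legend()), function(cl)
    sum(grid$codes == cl, na.rm = TRUE), numeric(1))
}

# kappa straight from its definition on a count matrix
bf_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

# figure of merit by cellwise enumeration of the four change categories
bf_fom <- function(o0, o1, s1) {
  A <- B <- C <- D <- 0
  for (i in seq_along(o0)) {
    if (is.na(o0[i]) || is.na(o1[i]) || is.na(s1[i])) next
    obs <- o0[i] != o1[i]
    sim <- o0[i] != s1[i]
    if (obs && !sim) A <- A + 1
    else if (obs && sim && o1[i] == s1[i]) B <- B + 1
    else if (obs && sim) C <- C + 1
    else if (!obs && sim) D <- D + 1
  }
  B / (A + B + C + D)
}

# random reallocation meeting the same per-class cell targets: the
# no-skill baseline for figure-of-merit comparisons
random_allocate <- function(base, target_cells, seed) {
  set.seed(seed)
  codes <- base$codes
  counts <- tabulate(codes[!is.na(codes)], nbins = 7)
  gap <- target_cells - counts
  for (j in which(gap > 0)) {
    donors <- which(!is.na(codes) & matrix(codes %in% which(gap < 0),
                                           nrow(codes), ncol(codes)))
    pick <- sample(donors, gap[j])
    codes[pick] <- j
    counts <- tabulate(codes[!is.na(codes)], nbins = 7)
    gap <- target_cells - counts
  }
  landuse_grid(codes, cell_size = base$cell_size, origin = base$origin)
}

# rank-based AUC of scores against binary labels
bf_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small synthetic world shared by the heavier tests (built once per run)
shared_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(nrow = 100, ncol = 100, seed = 42)
      evo <- evolve_landscape(spec, steps = 2)
      probs <- fit_development(evo$maps[[1]], evo$maps[[2]], evo$drivers,
                               seed = 1)
      cache <<- list(spec = spec, evo = evo, probs = probs)
    }
    cache
  }
})
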