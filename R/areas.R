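#' Per-class areas of a land-use grid
#'
#' Counts non-nodata cells per class and converts counts to area using the
#' cell size. Total mapped area is conserved across any simulation step.
#'
#' @param grid A [landuse_grid()].
#' @return A data frame with one row per legend class: `code`, `class`,
#'   `cells`, `area_ha`, `area_km2`.
#' @export
class_areas <- function(grid) {
  counts <- tabulate(grid$codes[!is.na(grid$codes)], nbins = max(grid$legend))
  counts <- counts[grid$legend]
  a_ha <- counts * cell_area_ha(grid)
  data.frame(code = unname(grid$legend), class = names(grid$legend),
             cells = counts, area_ha = a_ha, area_km2 = a_ha / 100,
             row.names = NULL)
}

#' Cross-tabulate two land-use maps
#'
#' Entry (i, j) is the area (ha) of cells coded i in `grid_a` and j in
#' `grid_b`; the diagonal is persistence. Row sums equal the per-class
#' areas of `grid_a` and the grand total equals the mapped area.
#'
#' @param grid_a,grid_b Aligned [landuse_grid()]s (same shape, cell size).
#' @param mask How to treat differing nodata masks: `"error"` (default)
#'   or `"intersect"` (warn and use the common mapped cells).
#' @return A K x K numeric matrix of areas in ha with class-name dimnames.
#' @export
crosstab <- function(grid_a, grid_b, mask = c("error", "intersect")) {
  na_any <- check_aligned(grid_a, grid_b, mask)
  keep <- !na_any
  lv <- grid_a$legend
  tab <- table(factor(grid_a$codes[keep], levels = lv),
               factor(grid_b$codes[keep], levels = lv))
  m <- unclass(tab) * cell_area_ha(grid_a)
  dimnames(m) <- list(from = names(lv), to = names(lv))
  m
}

#' Euclidean buffer mask around a target class
#'
#' True where the cell-center distance to the nearest cell of
#' `target_class` is at most `radius`. With `radius = 0` the mask equals
#' the target-class cells themselves.
#'
#' @param grid A [landuse_grid()].
#' @param target_class Integer class code.
#' @param radius Buffer radius in meters (>= 0).
#' @return Logical matrix of the grid's shape.
#' @export
buffer_mask <- function(grid, target_class, radius) {
  if (radius < 0) stop("`radius` must be non-negative")
  m <- grid$codes
  target <- !is.na(m) & m == target_class
  if (!any(target)) {
    warning("target class ", target_class, " absent; returning all-false mask")
    return(matrix(FALSE, nrow(m), ncol(m)))
  }
  cs <- grid$cell_size
  r_cells <- radius / cs
  ri <- floor(r_cells)
  # precompute the disc stamp of cell offsets within radius
  off <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  off <- off[off$dr^2 + off$dc^2 <= r_cells^2 + 1e-12, , drop = FALSE]
  out <- matrix(FALSE, nrow(m), ncol(m))
  idx <- which(target, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    rr <- idx[k, 1] + off$dr
    cc <- idx[k, 2] + off$dc
    keep <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
    out[cbind(rr[keep], cc[keep])] <- TRUE
  }
  out
}

#' Aggregate a fine matrix onto square blocks
#'
#' Each coarse cell aggregates the fine cells whose centers fall inside a
#' `block` x `block` meter window anchored at the grid origin; edge blocks
#' may be partial. With `fun = "sum"` the block totals conserve the global
#' sum.
#'
#' @param values Numeric matrix on the fine grid.
#' @param cell_size Fine cell size in meters.
#' @param block Block edge length in meters (>= `cell_size`).
#' @param fun `"sum"` or `"mean"` (mean over non-`NA` fine cells).
#' @param origin (x, y) of the fine grid's upper-left corner.
#' @return List with `values` (coarse matrix), `centers_x`, `centers_y`
#'   (block-center coordinate vectors), `block` and `cells` (count of
#'   contributing fine cells per block).
#' @export
block_aggregate <- function(values, cell_size, block, fun = c("sum", "mean"),
                            origin = c(0, 0)) {
  fun <- match.arg(fun)
  if (block < cell_size) stop("`block` must be at least the cell size")
  nr <- nrow(values); nc <- ncol(values)
  # block index of each fine row/col from cell-center offsets
  br <- pmin(floor(((seq_len(nr) - 0.5) * cell_size) / block) + 1L,
             ceiling(nr * cell_size / block))
  bc <- pmin(floor(((seq_len(nc) - 0.5) * cell_size) / block) + 1L,
             ceiling(nc * cell_size / block))
  nbr <- max(br); nbc <- max(bc)
  g <- (rep(bc, each = nr) - 1L) * nbr + rep(br, times = nc)
  v <- as.vector(values)
  ok <- !is.na(v)
  sums <- rowsum(v[ok], g[ok])
  cnts <- rowsum(rep(1L, sum(ok)), g[ok])
  out <- matrix(NA_real_, nbr, nbc)
  n_out <- matrix(0L, nbr, nbc)
  pos <- as.integer(rownames(sums))
  out[pos] <- if (fun == "sum") sums else sums / cnts
  n_out[pos] <- cnts
  list(values = out,
       centers_x = origin[1] + (seq_len(nbc) - 0.5) * block,
       centers_y = origin[2] - (seq_len(nbr) - 0.5) * block,
       block = block, cells = n_out)
}

#' Per-class cell counts aggregated onto blocks
#'
#' Convenience used by the coordination stage: one coarse count matrix per
#' legend class.
#'
#' @param grid A [landuse_grid()].
#' @param block Block edge length in meters.
#' @return List of coarse count matrices named by class, plus `centers_x`,
#'   `centers_y`.
#' @export
block_class_areas <- function(grid, block) {
  lv <- grid$legend
  out <- vector("list", length(lv))
  names(out) <- names(lv)
  cx <- cy <- NULL
  for (k in seq_along(lv)) {
    ind <- (!is.na(grid$codes) & grid$codes == lv[k]) * 1
    agg <- block_aggregate(ind, grid$cell_size, block, fun = "sum",
                           origin = grid$origin)
    out[[k]] <- agg$values
    cx <- agg$centers_x; cy <- agg$centers_y
  }
  c(out, list(centers_x = cx, centers_y = cy,
              cell_area_ha = cell_area_ha(grid)))
}
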