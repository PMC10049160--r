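#' Ordinal land-use intensity levels
#'
#' Disturbance levels by class: 1 unused land; 2 forests, grassland,
#' wetland and waters; 3 farmland; 4 construction land.
#'
#' @return Named numeric vector over the seven classes.
#' @export
intensity_levels <- function() {
  c(farmland = 3, forests = 2, grassland = 2, wetland = 2,
    waters = 2, construction = 4, unused = 1)
}

#' Land-use intensity of a block
#'
#' Area-weighted sum `sum_i level(i) * area_i`; with `normalize = TRUE`
#' the sum is divided by the block area, yielding a dimensionless mean
#' level.
#'
#' @param areas Named per-class areas within the block (any consistent
#'   unit).
#' @param levels Named intensity levels (default [intensity_levels()]).
#' @param normalize Divide by total area.
#' @return Intensity value.
#' @export
lui <- function(areas, levels = intensity_levels(), normalize = FALSE) {
  if (any(areas < 0)) stop("areas must be non-negative")
  if (is.null(names(areas))) names(areas) <- names(levels)
  v <- sum(levels[names(areas)] * areas)
  if (normalize) v / sum(areas) else v
}

#' Simple annualized growth rate
#'
#' `((v_t1 - v_t0) / v_t0) / years`; with `compound = TRUE`,
#' `(v_t1 / v_t0)^(1/years) - 1`. A zero base with a zero end value is
#' a zero rate; a zero base with a positive end value is undefined and
#' returns `NA` (the block is excluded downstream).
#'
#' @param v_t0,v_t1 Non-negative values at the two dates (vectorized).
#' @param years Interval length (> 0).
#' @param compound Use the compound formulation.
#' @return Rate per year (possibly `NA`).
#' @export
annual_growth <- function(v_t0, v_t1, years, compound = FALSE) {
  if (years <= 0) stop("`years` must be positive")
  if (any(v_t0 < 0, na.rm = TRUE) || any(v_t1 < 0, na.rm = TRUE))
    stop("values must be non-negative")
  out <- ifelse(v_t0 > 0,
                if (compound) (v_t1 / v_t0)^(1 / years) - 1
                else ((v_t1 - v_t0) / v_t0) / years,
                ifelse(v_t1 == 0, 0, NA_real_))
  out
}

#' Coordination index of two growth rates
#'
#' `O = |(alui + acs) / 2| / sqrt(alui^2 + acs^2)`, in `[0, 1]`:
#' 1 when the two rates are equal (balanced growth), 0 when exactly
#' opposed. Undefined (NA) when both rates are zero. Scale-invariant.
#'
#' @param alui,acs Annual growth rates (vectorized).
#' @return Index values in `[0, 1]` (`NA` where both rates are 0).
#' @export
coordination_index <- function(alui, acs) {
  norm <- sqrt(alui^2 + acs^2)
  ifelse(norm == 0, NA_real_, abs((alui + acs) / 2) / norm)
}

#' Classify a block's coordination
#'
#' `O` in `[0, 0.5)` is uncoordinated, `[0.5, 0.8)` adapted, `[0.8, 1]`
#' coordinated (the boundary 0.8 is assigned upward). The sub-label is
#' `"ahead"` when carbon-storage growth leads (`alui < acs`), else
#' `"lagging"`; exactly equal rates are labelled `"ahead"` by
#' convention. Undefined `O` gives `"no-change"`.
#'
#' @param o Coordination index (vectorized; `NA` allowed).
#' @param alui,acs The growth rates.
#' @return Character vector like `"adapted/ahead"`.
#' @export
classify_coordination <- function(o, alui, acs) {
  type <- ifelse(is.na(o), "no-change",
                 ifelse(o < 0.5, "uncoordinated",
                        ifelse(o < 0.8, "adapted", "coordinated")))
  sub <- ifelse(alui <= acs, "ahead", "lagging")
  ifelse(type == "no-change", type, paste(type, sub, sep = "/"))
}

#' Block-level coordination of land-use intensity and carbon storage
#'
#' Aggregates two dated maps onto square blocks (3 km default), computes
#' each block's land-use intensity and carbon storage at both dates,
#' annual growth rates, coordination index and class.
#'
#' @param grid_t0,grid_t1 Aligned [landuse_grid()]s at the two dates.
#' @param density_t0,density_t1 [carbon_density_table()]s; by default
#'   year-specific densities are used at each date (pass the same table
#'   twice for a fixed-density variant).
#' @param years Interval length in years.
#' @param block Block edge in meters (default 3000).
#' @param levels Intensity levels.
#' @return Data frame with one row per block containing centers, LUI and
#'   CS at both dates, `alui`, `acs`, `o` and `label`.
#' @export
coordination_grid <- function(grid_t0, grid_t1, density_t0, density_t1,
                              years = 10, block = 3000,
                              levels = intensity_levels()) {
  check_aligned(grid_t0, grid_t1)
  b0 <- block_class_areas(grid_t0, block)
  b1 <- block_class_areas(grid_t1, block)
  cls <- lu_classes()
  a_ha <- b0$cell_area_ha
  d0 <- stats::setNames(density_t0$total, density_t0$class)[cls]
  d1 <- stats::setNames(density_t1$total, density_t1$class)[cls]
  nb <- length(b0[[cls[1]]])
  lui0 <- lui1 <- cs0 <- cs1 <- rep(0, nb)
  for (i in seq_along(cls)) {
    c0 <- b0[[cls[i]]]; c0[is.na(c0)] <- 0
    c1 <- b1[[cls[i]]]; c1[is.na(c1)] <- 0
    lui0 <- lui0 + levels[[cls[i]]] * c0 * a_ha
    lui1 <- lui1 + levels[[cls[i]]] * c1 * a_ha
    cs0 <- cs0 + d0[[i]] * c0 * a_ha   # Mg
    cs1 <- cs1 + d1[[i]] * c1 * a_ha
  }
  alui <- annual_growth(lui0, lui1, years)
  acs <- annual_growth(cs0, cs1, years)
  o <- ifelse(is.na(alui) | is.na(acs), NA_real_,
              coordination_index(alui, acs))
  nbr <- nrow(b0[[cls[1]]])
  df <- data.frame(
    block_row = rep(seq_len(nbr), times = nb / nbr),
    block_col = rep(seq_len(nb / nbr), each = nbr),
    x = rep(b0$centers_x, each = nbr),
    y = rep(b0$centers_y, times = nb / nbr),
    lui_t0 = as.vector(lui0), lui_t1 = as.vector(lui1),
    cs_t0 = as.vector(cs0), cs_t1 = as.vector(cs1),
    alui = as.vector(alui), acs = as.vector(acs), o = as.vector(o))
  df$label <- classify_coordination(df$o, df$alui, df$acs)
  # drop blocks with no mapped cells at all (every class level is >= 1,
  # so any mapped cell gives a positive intensity)
  df[df$lui_t0 > 0 | df$lui_t1 > 0, ]
}
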