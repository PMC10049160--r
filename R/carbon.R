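#' Per-class four-pool carbon-density table
#'
#' Densities in Mg/ha for the aboveground-biomass, belowground-biomass,
#' soil and dead-organic-matter pools of each of the seven classes.
#' Waters carries zero in every pool (open water holds no accountable
#' vegetation or soil carbon in this scheme).
#'
#' @param df Data frame with columns `class`, `above`, `below`, `soil`,
#'   `dead` covering all seven classes.
#' @param year Year label.
#' @return Object of class `carbon_density_table` (the data frame with a
#'   `total` column and `year` attribute).
#' @export
carbon_density_table <- function(df, year = NA) {
  need <- c("class", "above", "below", "soil", "dead")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  missing_cls <- setdiff(lu_classes(), df$class)
  if (length(missing_cls)) stop("missing class rows: ",
                                paste(missing_cls, collapse = ", "))
  df <- df[match(lu_classes(), df$class), ]
  pools <- as.matrix(df[, c("above", "below", "soil", "dead")])
  if (any(pools < 0)) stop("densities must be non-negative")
  if (any(pools["waters" == df$class, ] != 0))
    stop("waters must have all-zero carbon pools")
  df$total <- rowSums(pools)
  structure(df, year = year, class = c("carbon_density_table", "data.frame"))
}

#' Read a carbon-density table from delimited text
#'
#' @param path TSV with columns `class`, `year`, `above`, `below`,
#'   `soil`, `dead` (possibly several years).
#' @param year Which year label to extract.
#' @return A [carbon_density_table()].
#' @export
read_density_table <- function(path, year) {
  df <- utils::read.delim(path)
  df <- df[df$year == year, ]
  if (nrow(df) == 0) stop("no rows for year ", year, " in ", path)
  carbon_density_table(df, year = year)
}

#' Bundled Dongting Lake Basin reference tables
#'
#' `dlb_carbon_density()` returns the basin's per-class four-pool carbon
#' densities for 2020 or 2030 (the 2030 values being GM(1,1) projections
#' of the 1980-2020 density series); `dlb_class_areas()` returns the
#' basin's per-class areas (km2) in 2020 and under the four 2030
#' scenarios. These ship with the package as delimited text under
#' `inst/extdata/`.
#'
#' @param year 2020 or 2030.
#' @return A [carbon_density_table()] / a data frame of areas.
#' @export
dlb_carbon_density <- function(year = 2020) {
  read_density_table(system.file("extdata", "dlb_carbon_density.tsv",
                                 package = "carbonscape", mustWork = TRUE),
                     year)
}

#' @rdname dlb_carbon_density
#' @export
dlb_class_areas <- function() {
  utils::read.delim(system.file("extdata", "dlb_class_areas.tsv",
                                package = "carbonscape", mustWork = TRUE))
}

#' @rdname dlb_carbon_density
#' @param label Area-table label, e.g. `"2020"` or `"2030_NES"`.
#' @export
dlb_area_vector <- function(label) {
  df <- dlb_class_areas()
  df <- df[df$label == label, ]
  if (nrow(df) == 0) stop("no areas labelled ", label)
  stats::setNames(df$area_km2 * 100, df$class)[lu_classes()]
}

#' Ecosystem carbon storage of a map or area table
#'
#' Per class, storage = area (ha) x summed pool density (Mg/ha); totals
#' are reported in Tg (1 Tg = 1e6 Mg). Accepts either a
#' [landuse_grid()] (optionally also returning a per-cell Mg map) or
#' per-class areas.
#'
#' @param x A [landuse_grid()], a [class_areas()] data frame, or a named
#'   vector of per-class areas in ha.
#' @param density A [carbon_density_table()].
#' @param per_cell If `TRUE` and `x` is a grid, also return the per-cell
#'   storage map (Mg per cell).
#' @return Object of class `carbon_result`: list with `per_class_tg`
#'   (named vector), `total_tg`, and optionally `map`.
#' @export
compute_cs <- function(x, density, per_cell = FALSE) {
  dens_total <- stats::setNames(density$total, density$class)
  if (inherits(x, "landuse_grid")) {
    areas <- stats::setNames(class_areas(x)$area_ha, lu_classes())
  } else {
    areas <- as_area_vector(x)
    if (is.null(names(areas))) names(areas) <- lu_classes()
  }
  if (!all(names(areas) %in% names(dens_total)))
    stop("density table does not cover: ",
         paste(setdiff(names(areas), names(dens_total)), collapse = ", "))
  per_class <- areas * dens_total[names(areas)] / 1e6
  out <- list(per_class_tg = per_class, total_tg = sum(per_class),
              year = attr(density, "year"))
  if (per_cell && inherits(x, "landuse_grid")) {
    m <- matrix(NA_real_, nrow(x$codes), ncol(x$codes))
    ok <- !is.na(x$codes)
    m[ok] <- dens_total[x$codes[ok]] * cell_area_ha(x)
    out$map <- m
  }
  structure(out, class = "carbon_result")
}

#' @export
print.carbon_result <- function(x, ...) {
  cat("<carbon_result>", if (!is.null(x$year) && !is.na(x$year))
    paste0("year ", x$year) else "", "\n")
  print(round(x$per_class_tg, 2))
  cat(sprintf("total: %.2f Tg\n", x$total_tg))
  invisible(x)
}

#' Carbon-storage change between two results
#'
#' @param result_a,result_b [compute_cs()] results over the same classes.
#' @return List with `per_class_tg` (b - a) and `total_tg`.
#' @export
cs_change <- function(result_a, result_b) {
  if (!identical(names(result_a$per_class_tg), names(result_b$per_class_tg)))
    stop("class sets differ")
  d <- result_b$per_class_tg - result_a$per_class_tg
  list(per_class_tg = d, total_tg = sum(d))
}

#' Carbon-storage flows of land transitions
#'
#' Decomposes map-change carbon effects by transition: entry (i, j) is
#' `area(i -> j) x (density(j) - density(i))` in 1e4 Mg, positive for a
#' carbon gain. By default both classes are valued at the horizon-year
#' densities, isolating the land-change effect; `from_at_start = TRUE`
#' values the source class at the start-year density instead.
#'
#' @param crosstab 7 x 7 transition area matrix (ha) from [crosstab()].
#' @param density_from,density_to [carbon_density_table()]s for the two
#'   dates.
#' @param from_at_start Use start-year density for the source class.
#' @return 7 x 7 matrix in 1e4 Mg, zero on the diagonal.
#' @export
transition_cs_flows <- function(crosstab, density_from, density_to,
                                from_at_start = FALSE) {
  d_to <- stats::setNames(density_to$total, density_to$class)[lu_classes()]
  d_from <- if (from_at_start)
    stats::setNames(density_from$total, density_from$class)[lu_classes()]
  else d_to
  per_ha <- outer(d_from, d_to, function(di, dj) dj - di)
  flows <- crosstab * per_ha / 1e4
  diag(flows) <- 0
  dimnames(flows) <- dimnames(crosstab)
  flows
}
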