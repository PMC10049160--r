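#' Default land-use legend
#'
#' The seven-class legend used throughout the package: 1 farmland,
#' 2 forests, 3 grassland, 4 wetland, 5 waters, 6 construction land,
#' 7 unused land.
#'
#' @return Named integer vector mapping class name to code.
#' @export
lu_legend <- function() {
  c(farmland = 1L, forests = 2L, grassland = 3L, wetland = 4L,
    waters = 5L, construction = 6L, unused = 7L)
}

#' Names of the seven land-use classes in code order
#' @return Character vector of length 7.
#' @export
lu_classes <- function() names(lu_legend())

#' Construct a categorical land-use grid
#'
#' A `landuse_grid` is an integer-coded raster on a regular square grid in
#' an equal-area projection. Codes follow [lu_legend()]; nodata cells are
#' stored as `NA` and are frozen throughout the pipeline: they are never
#' transitioned and never counted in areas. The coordinate convention is
#' row-major with the origin at the upper-left corner; the center of cell
#' (row, col) lies at `origin + (col - 0.5, -(row - 0.5)) * cell_size`.
#'
#' @param codes Integer matrix of class codes; `NA` marks nodata.
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin Numeric length-2, (x, y) of the upper-left corner.
#' @param legend Named integer vector mapping class names to codes.
#' @param nodata_code Integer written for `NA` cells on export.
#'
#' @return An object of class `landuse_grid`.
#' @export
landuse_grid <- function(codes, cell_size, origin = c(0, 0),
                         legend = lu_legend(), nodata_code = -9999L) {
  if (!is.matrix(codes)) stop("`codes` must be a matrix")
  storage.mode(codes) <- "integer"
  if (any(dim(codes) < 1L)) stop("grid dimensions must be at least 1x1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive length in meters")
  bad <- !is.na(codes) & !(codes %in% legend)
  if (any(bad))
    stop(sum(bad), " cell(s) carry codes outside the legend; use read_landuse() ",
         "to coerce out-of-legend values to nodata")
  if (all(is.na(codes))) stop("raster is entirely nodata")
  structure(
    list(codes = codes, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), legend = legend,
         nodata_code = as.integer(nodata_code)),
    class = "landuse_grid")
}

#' @export
print.landuse_grid <- function(x, ...) {
  d <- dim(x$codes)
  cat(sprintf("<landuse_grid> %d x %d cells, %.6g m cells (%.6g ha each)\n",
              d[1], d[2], x$cell_size, cell_area_ha(x)))
  cat(sprintf("  mapped cells: %d / %d\n", sum(!is.na(x$codes)), length(x$codes)))
  tab <- table(factor(x$codes, levels = x$legend,
                      labels = names(x$legend)))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Cell area of a grid in hectares
#' @param grid A `landuse_grid`.
#' @return Area of one cell in ha, `(cell_size / 100)^2`.
#' @export
cell_area_ha <- function(grid) (grid$cell_size / 100)^2

#' @export
dim.landuse_grid <- function(x) dim(x$codes)

#' Check two grids share shape, cell size and nodata mask
#' @noRd
check_aligned <- function(a, b, mask = c("error", "intersect")) {
  mask <- match.arg(mask)
  if (!identical(dim(a$codes), dim(b$codes)))
    stop("grids have different dimensions")
  if (!isTRUE(all.equal(a$cell_size, b$cell_size)))
    stop("grids have different cell sizes")
  na_a <- is.na(a$codes); na_b <- is.na(b$codes)
  if (!identical(na_a, na_b)) {
    if (mask == "error") stop("grids have different nodata masks")
    warning("nodata masks differ; intersecting masks")
  }
  na_a | na_b
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `nodata_value`) followed by row-major values from the top row down.
#'
#' @param path Path to a `.asc` file.
#' @return List with `values` (numeric matrix, `NA` for nodata),
#'   `cell_size`, and `origin` (upper-left corner).
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ESRI ASCII grid (missing ncols/nrows/cellsize): ", path)
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("expected ", nc * nr, " values, found ", length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  list(values = m, cell_size = cs, origin = c(xll, yll + nr * cs))
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values Numeric matrix (`NA` written as `nodata`).
#' @param path Output path.
#' @param cell_size Cell size in meters.
#' @param origin (x, y) upper-left corner.
#' @param nodata Nodata value to write.
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, path, cell_size, origin = c(0, 0),
                      nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  nr <- nrow(values); nc <- ncol(values)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", origin[1]),
           sprintf("yllcorner %.10g", origin[2] - nr * cell_size),
           sprintf("cellsize %.10g", cell_size),
           sprintf("nodata_value %.10g", nodata))
  out <- values
  out[is.na(out)] <- nodata
  body <- apply(out, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a land-use map from an ESRI ASCII grid
#'
#' Values must be integral; any value outside the legend (other than the
#' nodata value) is coerced to nodata with a warning reporting the count.
#'
#' @param path Path to a `.asc` file.
#' @param legend Named integer vector mapping class names to codes.
#' @return A validated [landuse_grid()].
#' @export
read_landuse <- function(path, legend = lu_legend()) {
  r <- read_asc(path)
  m <- r$values
  ok <- is.na(m) | abs(m - round(m)) < 1e-9
  if (!all(ok)) stop("band is not integer-valued: ", path)
  m <- round(m)
  out_of_legend <- !is.na(m) & !(m %in% legend)
  if (any(out_of_legend)) {
    warning(sum(out_of_legend), " cell(s) outside the legend mapped to nodata")
    m[out_of_legend] <- NA
  }
  storage.mode(m) <- "integer"
  landuse_grid(m, cell_size = r$cell_size, origin = r$origin, legend = legend)
}

#' Write a land-use map as an ESRI ASCII grid
#'
#' @param grid A `landuse_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landuse <- function(grid, path) {
  write_asc(grid$codes, path, cell_size = grid$cell_size,
            origin = grid$origin, nodata = grid$nodata_code)
}
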