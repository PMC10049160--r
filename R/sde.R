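#' Standard deviational ellipse of a weighted point set
#'
#' Summarizes the central tendency, dispersion and directional trend of
#' a point pattern: weighted mean center, rotation angle from the
#' standard SDE arctangent expression, and semiaxes equal to the
#' weighted standard deviations along the rotated axes (the default
#' `scale = 1`; `scale = sqrt(2)` gives the one-standard-deviation
#' coverage variant used by some GIS tools). The angle is measured
#' clockwise from north (grid +y).
#'
#' @param x,y Point coordinates.
#' @param w Non-negative weights (default unit).
#' @param scale Semiaxis scale factor.
#' @return Object of class `sd_ellipse`: list with `center`,
#'   `semi_major`, `semi_minor`, `angle_deg`, `area`, and `degenerate`
#'   (`TRUE` for collinear input).
#' @export
sde <- function(x, y, w = rep(1, length(x)), scale = 1) {
  if (length(x) != length(y) || length(x) != length(w))
    stop("x, y and w must have equal length")
  if (length(x) < 3) stop("at least 3 points are required")
  if (any(w < 0) || sum(w) == 0) stop("weights must be non-negative with a positive sum")
  W <- sum(w)
  cx <- sum(w * x) / W
  cy <- sum(w * y) / W
  dx <- x - cx
  dy <- y - cy
  sxx <- sum(w * dx^2)
  syy <- sum(w * dy^2)
  sxy <- sum(w * dx * dy)
  # rotation angle theta clockwise from north
  if (abs(sxy) < .Machine$double.eps * max(sxx, syy, 1)) {
    theta <- if (sxx >= syy) pi / 2 else 0
  } else {
    theta <- atan(((sxx - syy) + sqrt((sxx - syy)^2 + 4 * sxy^2)) / (2 * sxy))
    if (theta < 0) theta <- theta + pi
  }
  # axis-aligned (rotated) weighted standard deviations
  s1 <- sqrt(sum(w * (dx * cos(theta) - dy * sin(theta))^2) / W) * scale
  s2 <- sqrt(sum(w * (dx * sin(theta) + dy * cos(theta))^2) / W) * scale
  semi_major <- max(s1, s2)
  semi_minor <- min(s1, s2)
  # report the orientation of the major axis
  angle <- if (s1 >= s2) theta else theta + pi / 2
  angle <- angle %% pi
  structure(list(center = c(x = cx, y = cy),
                 semi_major = semi_major, semi_minor = semi_minor,
                 angle_deg = angle * 180 / pi,
                 area = pi * semi_major * semi_minor,
                 degenerate = semi_minor < .Machine$double.eps^0.5 *
                   max(semi_major, 1)),
            class = "sd_ellipse")
}

#' @export
print.sd_ellipse <- function(x, ...) {
  cat(sprintf(paste0("<sd_ellipse> center (%.3f, %.3f), semiaxes %.4f / %.4f,",
                     " angle %.2f deg, area %.4f%s\n"),
              x$center[1], x$center[2], x$semi_major, x$semi_minor,
              x$angle_deg, x$area, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
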