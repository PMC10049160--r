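#' Fit a GM(1,1) gray model
#'
#' Standard construction: the first-order accumulated generating
#' operation (1-AGO) gives `x1 = cumsum(x0)`; background values
#' `z1(k) = (x1(k) + x1(k-1)) / 2`; least squares on
#' `x0(k) = -a z1(k) + b` yields the development coefficient `a` and
#' gray action quantity `b`. For an exact geometric input
#' `c * r^(k-1)` the fit is exact with `a = -2(r-1)/(r+1)` and
#' `b = 2c/(r+1)`; a constant series gives `(a, b) = (0, c)`.
#'
#' @param series Strictly positive numeric vector, length >= 4.
#' @return Object of class `gm11_model`: list with `a`, `b`, `x1`
#'   (first observation), `n`, and in-sample `fitted` values.
#' @export
gm11_fit <- function(series) {
  if (length(series) < 4) stop("GM(1,1) needs at least 4 observations")
  if (any(!is.finite(series)) || any(series <= 0))
    stop("GM(1,1) requires a strictly positive series")
  x1 <- cumsum(series)
  n <- length(series)
  z <- (x1[-1] + x1[-n]) / 2
  B <- cbind(-z, 1)
  Y <- series[-1]
  ab <- solve(crossprod(B), crossprod(B, Y))
  model <- structure(list(a = ab[1], b = ab[2], x1 = series[1], n = n),
                     class = "gm11_model")
  model$fitted <- vapply(seq_len(n), function(k) gm11_predict(model, k),
                         numeric(1))
  model
}

#' Restored-value prediction from a GM(1,1) model
#'
#' `x0_hat(1)` is the first observation; for `k >= 2`,
#' `x0_hat(k) = (x0(1) - b/a) (1 - exp(a)) exp(-a (k - 1))`. The
#' degenerate `a = 0` case is the constant limit `b`.
#'
#' @param model A [gm11_fit()] model.
#' @param k Index (1 = first observation; `model$n + h` forecasts h
#'   steps ahead). Vectorized.
#' @return Numeric vector of restored values.
#' @export
gm11_predict <- function(model, k) {
  if (any(k < 1)) stop("`k` must be >= 1")
  a <- model$a; b <- model$b; x0_1 <- model$x1
  out <- if (abs(a) < 1e-12) rep(b, length(k))
  else (x0_1 - b / a) * (1 - exp(a)) * exp(-a * (k - 1))
  out[k == 1] <- x0_1
  out
}

#' Forecast a series h steps ahead with GM(1,1)
#'
#' @param series Strictly positive series (length >= 4).
#' @param h Steps beyond the last observation.
#' @return Numeric vector of `h` forecasts.
#' @export
gm11_forecast <- function(series, h = 1L) {
  model <- gm11_fit(series)
  gm11_predict(model, model$n + seq_len(h))
}
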