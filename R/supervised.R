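#' Sliding-window supervised conversion
#'
#' Converts a daily series into one-step-ahead supervised samples: input
#' `i` is days `i ... i+lookback-1`, target `i` is day `i+lookback`. A
#' series of length `L` yields exactly `L - lookback` pairs.
#'
#' @param series numeric vector (or `daily_series`).
#' @param lookback window length in days (default 7: the forecaster learns
#'   on week-long histories and predicts the eighth day).
#' @return `list(inputs = <n x lookback matrix>, targets = <n vector>,
#'   lookback)`.
#' @export
to_supervised <- function(series, lookback = 7L) {
  v <- if (inherits(series, "daily_series")) series$values else as.numeric(series)
  L <- length(v)
  if (L <= lookback)
    stop("series length (", L, ") must exceed lookback (", lookback, ")",
         call. = FALSE)
  n <- L - lookback
  inputs <- t(vapply(seq_len(n), function(i) v[i:(i + lookback - 1L)],
                     numeric(lookback)))
  list(inputs = inputs, targets = v[(lookback + 1L):L], lookback = lookback)
}

#' Per-user min-max scaling
#'
#' Maps a series onto `[0, 1]`. Constant (including all-zero) series map to
#' zeros, with an inverse that restores the constant exactly.
#'
#' @param series numeric vector.
#' @return `list(scaled, transform = list(min, range))`.
#' @export
scale_series <- function(series) {
  v <- if (inherits(series, "daily_series")) series$values else as.numeric(series)
  mn <- min(v)
  rg <- max(v) - mn
  scaled <- if (rg > 0) (v - mn) / rg else rep(0, length(v))
  list(scaled = scaled, transform = list(min = mn, range = rg))
}

#' Apply / invert a min-max transform
#'
#' @param transform a transform from [scale_series()].
#' @param x values on the original (seconds) axis for `apply_scale`, or on
#'   the `[0, 1]` axis for `inverse_scale`.
#' @return Transformed values.
#' @export
inverse_scale <- function(transform, x) {
  if (transform$range > 0) x * transform$range + transform$min
  else x * 0 + transform$min
}

#' @rdname inverse_scale
#' @export
apply_scale <- function(transform, x) {
  if (transform$range > 0) (x - transform$min) / transform$range
  else x * 0
}
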