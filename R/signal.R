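#' Low-pass filter specification
#'
#' Parameters of the Butterworth low-pass applied identically to distance
#' and marker data before analysis: order 4, 6 Hz cutoff by default. In
#' zero-phase mode the filter is run forward and backward (no group delay,
#' so event timing is unbiased); the cutoff is the nominal design cutoff of
#' a single pass, so the effective two-pass magnitude response is
#' `|H(f)|^2` with `|H(f)| = (1 + (f/fc)^(2*order))^(-1/2)`.
#'
#' @param order Filter order; even, at least 2.
#' @param cutoff_hz Cutoff frequency, Hz; must be below Nyquist at
#'   application time.
#' @param zero_phase Run forward-backward (default) or causal.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(order = 4L, cutoff_hz = 6, zero_phase = TRUE) {
  if (order < 2 || order %% 2 != 0) abort("`order` must be even and >= 2")
  if (cutoff_hz <= 0) abort("`cutoff_hz` must be positive")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Butterworth low-pass filter
#'
#' Filters a uniformly sampled numeric vector with a Butterworth low-pass
#' designed at `spec$cutoff_hz`. Edge effects are controlled by odd
#' (point-reflected) padding of length `3 * order` samples at both ends,
#' which preserves the signal level and slope across the boundary; the
#' padding is stripped from the output, so length and timestamps are
#' unchanged. Zero-phase mode applies the same filter forward then backward.
#'
#' @param x Numeric vector, uniformly sampled, no missing values.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length as `x`.
#' @examples
#' butterworth_lowpass(rep(1, 100), fs = 30)  # DC gain 1
#' @export
butterworth_lowpass <- function(x, fs, spec = filter_spec()) {
  if (!inherits(spec, "filter_spec")) abort("`spec` must be a filter_spec()")
  if (anyNA(x)) abort("`x` contains missing values; fill or exclude gaps first")
  if (spec$cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff %g Hz is at or above Nyquist (%g Hz)",
                  spec$cutoff_hz, fs / 2))
  }
  n <- length(x)
  pad <- 3L * spec$order
  if (n <= pad) {
    abort(sprintf("series too short to filter: need > %d samples, got %d", pad, n))
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  # odd reflection about the end samples: 2*x[1] - x[k] etc.
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xe <- c(left, x, right)
  # the filter starts from rest; running it on the level-shifted signal
  # (first sample at zero) suppresses the DC startup transient exactly,
  # since the DC gain is 1
  run <- function(z) as.numeric(signal::filter(bf, z - z[1L])) + z[1L]
  y <- run(xe)
  if (spec$zero_phase) {
    y <- rev(run(rev(y)))
  }
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter every value column of a series
#'
#' Applies [butterworth_lowpass()] to each numeric column except `t`.
#' All samples must be valid; interpolate isolated gaps with
#' [fill_invalid()] first.
#'
#' @param df A series tibble.
#' @param spec A [filter_spec()].
#' @param cols Columns to filter; defaults to all numeric value columns.
#' @return The series with filtered value columns.
#' @export
filter_series <- function(df, spec = filter_spec(), cols = NULL) {
  fs <- series_fs(df)
  cols <- cols %||% series_value_cols(df)
  if ("valid" %in% names(df) && !all(df$valid)) {
    abort("series contains invalid samples; fill_invalid() or trim before filtering")
  }
  for (col in cols) {
    df[[col]] <- butterworth_lowpass(df[[col]], fs, spec)
  }
  df
}

#' Cubic-spline resampling
#'
#' Resamples a uniformly sampled vector onto a uniform grid at `fs_out`
#' spanning the same interval, by cubic-spline interpolation (`stats`
#' "fmm" spline, which reproduces cubic polynomials exactly). The first
#' endpoint is always preserved; the last is preserved whenever it falls on
#' the output grid.
#'
#' @param x Numeric vector (length >= 4) or series tibble.
#' @param fs_in Input sampling rate, Hz (ignored for tibbles, taken from `t`).
#' @param fs_out Output sampling rate, Hz.
#' @return For vector input, a tibble with `t` and `x`; for a series tibble,
#'   the resampled series.
#' @export
spline_resample <- function(x, fs_in, fs_out) {
  if (is.data.frame(x)) return(resample_series(x, fs_out))
  if (length(x) < 4L) abort("need at least 4 samples for cubic-spline resampling")
  if (fs_in <= 0 || fs_out <= 0) abort("sampling rates must be positive")
  t_in <- (seq_along(x) - 1L) / fs_in
  t_out <- seq(t_in[1L], t_in[length(t_in)] + 1e-9 / fs_out, by = 1 / fs_out)
  t_out <- t_out[t_out <= t_in[length(t_in)] + 1e-9 / fs_out]
  sf <- splinefun(t_in, x, method = "fmm")
  tibble(t = t_out, x = sf(t_out))
}

#' @param df A series tibble.
#' @rdname spline_resample
#' @export
resample_series <- function(df, fs_out) {
  fs_in <- series_fs(df)
  if (nrow(df) < 4L) abort("need at least 4 samples for cubic-spline resampling")
  if ("valid" %in% names(df) && !all(df$valid)) {
    abort("series contains invalid samples; fill_invalid() or trim before resampling")
  }
  n <- nrow(df)
  t_out <- df$t[1L] + seq(0, df$t[n] - df$t[1L] + 1e-9 / fs_out, by = 1 / fs_out)
  t_out <- t_out[t_out <= df$t[n] + 1e-9 / fs_out]
  out <- tibble(t = t_out)
  for (col in series_value_cols(df)) {
    out[[col]] <- splinefun(df$t, df[[col]], method = "fmm")(t_out)
  }
  for (col in setdiff(names(df), c("t", series_value_cols(df)))) {
    if (col == "valid") {
      out$valid <- TRUE
    } else {
      out[[col]] <- df[[col]][1L]
    }
  }
  out[names(df)]
}
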