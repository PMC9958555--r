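#' Waveform similarity between two angle segments
#'
#' Zero-lag normalised correlation (the mean-removed inner product over the
#' product of standard deviations, i.e. the Pearson coefficient of the
#' time-aligned samples) between two segments covering the same phase. The
#' segments are truncated from the start to their common length. Because the
#' exact estimator behind published "cross-correlation" waveform
#' comparisons is often ambiguous, `lag_mode = "max"` instead returns the
#' maximum coefficient over integer-sample lags within `max_lag_s`.
#'
#' @param a,b Numeric segments (degrees), same sampling rate, no missing
#'   values, length >= 3 after truncation.
#' @param lag_mode `"zero"` (default) or `"max"`.
#' @param fs Sampling rate, Hz; required for `lag_mode = "max"`.
#' @param max_lag_s Lag search half-window, seconds.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
waveform_similarity <- function(a, b, lag_mode = c("zero", "max"),
                                fs = NULL, max_lag_s = 0.2) {
  lag_mode <- match.arg(lag_mode)
  if (anyNA(a) || anyNA(b)) abort("segments contain missing values")
  n <- min(length(a), length(b))
  if (n < 3L) abort("segments too short: need length >= 3")
  a <- a[seq_len(n)]
  b <- b[seq_len(n)]
  if (sd(a) == 0 || sd(b) == 0) abort("degenerate segment (zero variance)")
  if (lag_mode == "zero") return(cor(a, b))
  if (is.null(fs)) abort("`fs` is required for lag_mode = \"max\"")
  max_lag <- max(0L, as.integer(round(max_lag_s * fs)))
  best <- -Inf
  for (lag in (-max_lag):max_lag) {
    if (lag >= 0) {
      ai <- seq.int(1L + lag, n)
      bi <- seq.int(1L, n - lag)
    } else {
      ai <- seq.int(1L, n + lag)
      bi <- seq.int(1L - lag, n)
    }
    if (length(ai) < 3L) next
    if (sd(a[ai]) == 0 || sd(b[bi]) == 0) next
    best <- max(best, cor(a[ai], b[bi]))
  }
  if (!is.finite(best)) abort("degenerate segment (zero variance at all lags)")
  best
}

#' Fisher r-to-z averaged correlation
#'
#' Averages correlation coefficients on the variance-stabilised z scale and
#' transforms back: `tanh(mean(atanh(r)))`. This avoids floor/ceiling
#' compression when averaging coefficients near 1. Coefficients at or
#' beyond the transform's ceiling (`|r| >= 1`) are clipped to
#' `1 - 1e-7` in magnitude, with a warning.
#'
#' @param rs Numeric vector of correlation coefficients, non-empty.
#' @return The averaged coefficient.
#' @examples
#' fisher_mean(c(0.9, 0.5))  # 0.7661
#' @export
fisher_mean <- function(rs) {
  if (length(rs) == 0L || anyNA(rs)) {
    abort("`rs` must be a non-empty vector of correlations without NA")
  }
  if (any(abs(rs) > 1)) abort("correlations must lie in [-1, 1]")
  if (any(abs(rs) == 1)) {
    warn("correlation(s) of magnitude 1 clipped to 1 - 1e-7 before Fisher transform")
    rs <- sign(rs) * pmin(abs(rs), 1 - 1e-7)
  }
  tanh(mean(atanh(rs)))
}

#' Excursion errors between chair-model and reference
#'
#' Absolute error in degrees and, where the reference excursion is
#' positive, the percentage of absolute error (100 * abs error /
#' reference excursion). A zero reference leaves the percentage `NA`.
#'
#' @param chair,ref One-row excursion tibbles from [excursions()] (columns
#'   `flexion_deg`, `extension_deg`).
#' @return A tibble with one row per phase: `phase`, `chair_deg`,
#'   `ref_deg`, `abs_err_deg`, `pct_err`.
#' @export
excursion_errors <- function(chair, ref) {
  for (x in list(chair, ref)) {
    if (!is.data.frame(x) || !all(c("flexion_deg", "extension_deg") %in% names(x))) {
      abort("excursion inputs must have columns flexion_deg, extension_deg")
    }
  }
  ch <- c(chair$flexion_deg[1L], chair$extension_deg[1L])
  rf <- c(ref$flexion_deg[1L], ref$extension_deg[1L])
  abs_err <- abs(ch - rf)
  pct <- ifelse(rf > 0, 100 * abs_err / rf, NA_real_)
  tibble(
    phase = c("flexion", "extension"),
    chair_deg = ch, ref_deg = rf,
    abs_err_deg = abs_err, pct_err = pct
  )
}

#' Across-trial agreement of excursions
#'
#' Pearson product-moment correlation between chair-model and reference
#' excursions pooled over trials (all conditions together).
#'
#' @param xs,ys Equal-length numeric vectors (length >= 3).
#' @return Pearson correlation coefficient.
#' @export
across_trial_correlation <- function(xs, ys) {
  if (length(xs) != length(ys)) abort("`xs` and `ys` must have equal length")
  if (length(xs) < 3L) abort("need at least 3 trials")
  if (anyNA(xs) || anyNA(ys)) abort("inputs contain missing values")
  if (sd(xs) == 0 || sd(ys) == 0) abort("zero variance input")
  cor(xs, ys)
}

# extract one phase segment from an angle series, clean NA edges and
# interpolate interior NA, return numeric vector
phase_segment <- function(series, from, to, col) {
  x <- series[[col]][from:to]
  t <- series$t[from:to]
  ok <- !is.na(x)
  if (!any(ok)) abort("phase segment contains no valid samples")
  first <- which(ok)[1L]
  last <- tail(which(ok), 1L)
  x <- x[first:last]
  t <- t[first:last]
  if (anyNA(x)) {
    x <- approx(t[!is.na(x)], x[!is.na(x)], xout = t)$y
  }
  x
}

# phase-normalised alignment: spline both segments to the shorter one's
# sample count on a common 0..1 phase grid
align_segments <- function(a, b) {
  n <- min(length(a), length(b))
  resample_to <- function(x, n) {
    if (length(x) == n) return(x)
    splinefun(seq(0, 1, length.out = length(x)), x, method = "fmm")(
      seq(0, 1, length.out = n))
  }
  list(a = resample_to(a, n), b = resample_to(b, n))
}

#' Validate one trial of chair-model angles against a reference
#'
#' Runs the full per-trial concurrent-validity comparison. Both series are
#' first restricted to their jointly valid time span (agreement can only be
#' assessed where both systems report valid data; the chair model, for
#' instance, is singular for a perfectly vertical thigh, so its last
#' standing samples may be invalid). Each series is then
#' segmented by its own trunk events ([detect_sts_start()],
#' [segment_phases()]); trunk waveform similarity is computed separately
#' for the flexion and extension phases, thigh similarity over the whole
#' onset-to-maximum-extension window; phase segments of unequal duration
#' are phase-normalised by spline resampling to the shorter segment's
#' sample count. Trunk excursions from both systems give absolute and
#' percentage errors per phase.
#'
#' @param chair Chair-model angle series (30 Hz).
#' @param reference Reference (e.g. marker-based) angle series at the same
#'   sampling rate.
#' @param lag_mode,max_lag_s Passed to [waveform_similarity()].
#' @param threshold_deg,baseline_window_s Passed to [detect_sts_start()].
#' @return An object of class `sts_validation`: list with `metrics` (one-row
#'   tibble: `r_thigh`, `r_trunk_flexion`, `r_trunk_extension`,
#'   `abs_err_flexion_deg`, `abs_err_extension_deg`, `pct_err_flexion`,
#'   `pct_err_extension`), `segmentation` (two-row tibble), `excursions`
#'   (two-row tibble), `errors` (from [excursion_errors()]).
#' @export
validate_trial <- function(chair, reference, lag_mode = c("zero", "max"),
                           max_lag_s = 0.2, threshold_deg = 1.0,
                           baseline_window_s = 0.5) {
  lag_mode <- match.arg(lag_mode)
  check_series(chair, "angle")
  check_series(reference, "angle")
  fs_c <- series_fs(chair)
  fs_r <- series_fs(reference)
  if (abs(fs_c - fs_r) > 1e-6 * fs_c) {
    abort("chair and reference series must share a sampling rate; resample first")
  }

  # restrict to the time span where both systems deliver valid samples
  span_of <- function(s) {
    val <- if ("valid" %in% names(s)) as.logical(s$valid) else rep(TRUE, nrow(s))
    v <- which(val & !is.na(s$theta_trunk_deg))
    if (length(v) == 0L) abort("series has no valid trunk samples")
    c(s$t[v[1L]], s$t[v[length(v)]])
  }
  b1 <- span_of(chair)
  b2 <- span_of(reference)
  lo <- max(b1[1L], b2[1L]) - 1e-9
  hi <- min(b1[2L], b2[2L]) + 1e-9
  chair <- chair[chair$t >= lo & chair$t <= hi, ]
  reference <- reference[reference$t >= lo & reference$t <= hi, ]
  if (nrow(chair) < 3L || nrow(reference) < 3L) {
    abort("chair and reference series share too few valid samples")
  }

  seg_of <- function(s) {
    start <- detect_sts_start(s, threshold_deg = threshold_deg,
                              baseline_window_s = baseline_window_s)
    segment_phases(s, start, baseline_window_s = baseline_window_s)
  }
  seg_c <- seg_of(chair)
  seg_r <- seg_of(reference)

  sim <- function(col, from_c, to_c, from_r, to_r) {
    seg <- align_segments(
      phase_segment(chair, from_c, to_c, col),
      phase_segment(reference, from_r, to_r, col)
    )
    waveform_similarity(seg$a, seg$b, lag_mode = lag_mode, fs = fs_c,
                        max_lag_s = max_lag_s)
  }
  r_flex <- sim("theta_trunk_deg", seg_c$start_idx, seg_c$max_flexion_idx,
                seg_r$start_idx, seg_r$max_flexion_idx)
  r_ext <- sim("theta_trunk_deg", seg_c$max_flexion_idx, seg_c$max_extension_idx,
               seg_r$max_flexion_idx, seg_r$max_extension_idx)
  r_thigh <- sim("theta_thigh_deg", seg_c$start_idx, seg_c$max_extension_idx,
                 seg_r$start_idx, seg_r$max_extension_idx)

  exc_c <- excursions(chair, seg_c)
  exc_r <- excursions(reference, seg_r)
  err <- excursion_errors(exc_c, exc_r)

  metrics <- tibble(
    r_thigh = r_thigh,
    r_trunk_flexion = r_flex,
    r_trunk_extension = r_ext,
    abs_err_flexion_deg = err$abs_err_deg[err$phase == "flexion"],
    abs_err_extension_deg = err$abs_err_deg[err$phase == "extension"],
    pct_err_flexion = err$pct_err[err$phase == "flexion"],
    pct_err_extension = err$pct_err[err$phase == "extension"]
  )
  structure(
    list(
      metrics = metrics,
      segmentation = dplyr::bind_rows(
        dplyr::mutate(seg_c, series = "chair", .before = 1L),
        dplyr::mutate(seg_r, series = "reference", .before = 1L)
      ),
      excursions = dplyr::bind_rows(
        dplyr::mutate(exc_c, series = "chair", .before = 1L),
        dplyr::mutate(exc_r, series = "reference", .before = 1L)
      ),
      errors = err,
      options = list(lag_mode = lag_mode, max_lag_s = max_lag_s,
                     threshold_deg = threshold_deg,
                     baseline_window_s = baseline_window_s)
    ),
    class = "sts_validation"
  )
}

#' @export
print.sts_validation <- function(x, ...) {
  cat("<sts_validation>\n")
  m <- x$metrics
  cat(sprintf("  similarity : thigh %.4f | trunk flexion %.4f | trunk extension %.4f\n",
              m$r_thigh, m$r_trunk_flexion, m$r_trunk_extension))
  cat(sprintf("  abs error  : flexion %.2f deg (%.1f%%) | extension %.2f deg (%.1f%%)\n",
              m$abs_err_flexion_deg, m$pct_err_flexion,
              m$abs_err_extension_deg, m$pct_err_extension))
  invisible(x)
}

#' Tidy a trial validation
#'
#' @param x An `sts_validation` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble with columns `metric`, `value`;
#'   `glance()`: the one-row metrics tibble.
#' @method tidy sts_validation
#' @export
tidy.sts_validation <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.sts_validation
#' @method glance sts_validation
#' @export
glance.sts_validation <- function(x, ...) x$metrics

#' Condition-level summary of trial validations
#'
#' Averages per-trial metrics within conditions the way repeated trials are
#' pooled in concurrent-validity studies: correlation columns are averaged
#' through [fisher_mean()] (r-to-z, mean, z-to-r); error columns are
#' arithmetic means.
#'
#' @param trials A tibble with one row per trial: a `condition` column plus
#'   the metric columns of [validate_trial()] (`r_*`, `abs_err_*`,
#'   `pct_err_*`).
#' @return A tibble with one row per condition: `condition`, `n_trials`,
#'   Fisher-averaged `r_*` columns and mean error columns.
#' @export
summarize_validations <- function(trials) {
  if (!is.data.frame(trials) || !"condition" %in% names(trials)) {
    abort("`trials` must be a data frame with a `condition` column")
  }
  r_cols <- grep("^r_", names(trials), value = TRUE)
  err_cols <- grep("^(abs_err|pct_err)", names(trials), value = TRUE)
  trials |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      dplyr::across(dplyr::all_of(r_cols), fisher_mean),
      dplyr::across(dplyr::all_of(err_cols), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}
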