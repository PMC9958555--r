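#' Detect the start of the sit-to-stand motion
#'
#' The trial must begin in quiet sitting. The baseline is the mean trunk
#' angle over the first `baseline_window_s` seconds; STS onset is the first
#' sample whose trunk angle exceeds the baseline by at least `threshold_deg`
#' (1 degree by default) *and* that starts a non-decreasing run of
#' `confirm_samples` further samples, which suppresses isolated
#' noise-triggered crossings.
#'
#' @param trunk An angle series tibble (see [series]); detection runs on
#'   `col`.
#' @param threshold_deg Onset threshold above baseline, degrees.
#' @param baseline_window_s Length of the quiet-sitting baseline window, s.
#' @param confirm_samples Number of following samples that must be
#'   non-decreasing to accept a crossing.
#' @param col Column holding the trunk angle.
#' @return Integer sample index (1-based) of STS onset.
#' @export
detect_sts_start <- function(trunk, threshold_deg = 1.0,
                             baseline_window_s = 0.5,
                             confirm_samples = 3L,
                             col = "theta_trunk_deg") {
  check_series(trunk, "angle")
  x <- trunk[[col]]
  n <- length(x)
  base_idx <- which(trunk$t < trunk$t[1L] + baseline_window_s)
  if (length(base_idx) == 0L) base_idx <- 1L
  baseline <- mean(x[base_idx], na.rm = TRUE)
  if (!is.finite(baseline)) abort("baseline window contains no valid samples")
  crossed <- which(!is.na(x) & x >= baseline + threshold_deg)
  for (i in crossed) {
    j <- i:min(n, i + confirm_samples)
    seg <- x[j]
    if (!anyNA(seg) && all(diff(seg) >= 0)) return(i)
  }
  abort("no STS onset detected")
}

#' Segment a trial into flexion and extension phases
#'
#' The flexion phase runs from STS onset to the maximum trunk flexion angle
#' (first sample of a tied maximum); the extension phase runs from that peak
#' to the maximum trunk extension, taken as the global post-peak minimum
#' (first sample of a tie). Phase boundaries are always defined on the trunk
#' series and applied to both trunk and thigh analyses.
#'
#' @param trunk An angle series tibble.
#' @param start_idx STS onset index, from [detect_sts_start()].
#' @param tol Flexion-peak tie tolerance, degrees (float-level ties only:
#'   the earliest of tied peak samples is chosen).
#' @param end_tol Extension-end plateau tolerance, degrees: the extension
#'   boundary is the earliest post-peak sample within `end_tol` of the
#'   post-peak minimum. After standing the trunk angle plateaus, so the
#'   literal global minimum lands on an arbitrary late sample under
#'   float-level or residual-filter wiggle; the plateau tolerance pins the
#'   boundary to where maximum extension is first reached. 0.05 degrees is
#'   far below any meaningful angular resolution.
#' @inheritParams detect_sts_start
#' @return A one-row tibble with `start_idx`, `max_flexion_idx`,
#'   `max_extension_idx`, `baseline_deg`, and the corresponding times
#'   `start_s`, `max_flexion_s`, `max_extension_s`.
#' @export
segment_phases <- function(trunk, start_idx, baseline_window_s = 0.5,
                           col = "theta_trunk_deg", tol = 1e-6,
                           end_tol = 0.05) {
  check_series(trunk, "angle")
  x <- trunk[[col]]
  n <- length(x)
  if (start_idx < 1L || start_idx > n) abort("`start_idx` out of bounds")
  base_idx <- which(trunk$t < trunk$t[1L] + baseline_window_s)
  if (length(base_idx) == 0L) base_idx <- 1L
  baseline <- mean(x[base_idx], na.rm = TRUE)

  post <- x[start_idx:n]
  flex_rel <- which(!is.na(post) & post >= max(post, na.rm = TRUE) - tol)[1L]
  max_flexion_idx <- start_idx + flex_rel - 1L
  if (max_flexion_idx >= n || max_flexion_idx <= start_idx) {
    abort("no trunk flexion peak found after onset (monotone series?)")
  }
  post2 <- x[max_flexion_idx:n]
  ext_rel <- which(!is.na(post2) & post2 <= min(post2, na.rm = TRUE) + end_tol)[1L]
  max_extension_idx <- max_flexion_idx + ext_rel - 1L
  if (max_extension_idx <= max_flexion_idx) {
    abort("no extension phase found after the flexion peak")
  }
  tibble(
    start_idx = as.integer(start_idx),
    max_flexion_idx = as.integer(max_flexion_idx),
    max_extension_idx = as.integer(max_extension_idx),
    baseline_deg = baseline,
    start_s = trunk$t[start_idx],
    max_flexion_s = trunk$t[max_flexion_idx],
    max_extension_s = trunk$t[max_extension_idx]
  )
}

#' Angular excursions of the two phases
#'
#' Maximum displacement within each phase: flexion excursion is the trunk
#' angle at peak flexion minus the angle at onset; extension excursion is
#' the angle at peak flexion minus the angle at maximum extension. Both are
#' invariant to adding a constant to the whole series.
#'
#' @param trunk An angle series tibble.
#' @param seg Segmentation from [segment_phases()].
#' @inheritParams detect_sts_start
#' @return A one-row tibble with `flexion_deg` and `extension_deg`.
#' @export
excursions <- function(trunk, seg, col = "theta_trunk_deg") {
  check_series(trunk, "angle")
  x <- trunk[[col]]
  n <- length(x)
  idx <- c(seg$start_idx, seg$max_flexion_idx, seg$max_extension_idx)
  if (any(idx < 1L | idx > n) || is.unsorted(idx)) {
    abort("segmentation indices out of bounds for this series")
  }
  tibble(
    flexion_deg = x[seg$max_flexion_idx] - x[seg$start_idx],
    extension_deg = x[seg$max_flexion_idx] - x[seg$max_extension_idx]
  )
}
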