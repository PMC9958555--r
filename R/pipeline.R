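#' Pre-process a distance series and convert to chair-model angles
#'
#' The standard chain for laser data: isolated invalid samples are
#' linearly interpolated ([fill_invalid()]), the series is trimmed to its
#' valid core (leading/trailing invalid samples dropped), both distance
#' channels are low-pass filtered ([butterworth_lowpass()]) at the native
#' rate, and the two-link inversion ([sts_angles()]) is applied.
#'
#' @param distances A distance series tibble.
#' @param geom A [chair_geometry()].
#' @param filter A [filter_spec()], or `NULL` to skip filtering.
#' @param max_gap Longest invalid run filled by interpolation, samples.
#' @return A chair-model angle series tibble at the input rate.
#' @export
process_distances <- function(distances, geom = chair_geometry(),
                              filter = filter_spec(), max_gap = 5L) {
  check_series(distances, "distance")
  if (!"valid" %in% names(distances)) distances$valid <- TRUE
  distances$valid <- distances$valid &
    !is.na(distances$d_thigh_mm) & !is.na(distances$d_trunk_mm)
  distances <- fill_invalid(distances, max_gap = max_gap)
  v <- which(distances$valid)
  if (length(v) == 0L) abort("distance series has no valid samples")
  distances <- distances[v[1L]:v[length(v)], ]
  if (!all(distances$valid)) {
    abort(sprintf("distance series has interior invalid runs longer than %d samples",
                  max_gap))
  }
  if (!is.null(filter)) distances <- filter_series(distances, filter)
  sts_angles(distances, geom)
}

#' Pre-process a marker series and convert to reference angles
#'
#' The standard chain for optical data: low-pass filter every marker
#' coordinate at the native rate ([butterworth_lowpass()]), spline-resample
#' to `fs_out` ([resample_series()]), then compute marker-based segment
#' angles ([marker_angles()]).
#'
#' @param markers A marker series tibble (typically 100 Hz).
#' @param filter A [filter_spec()], or `NULL` to skip filtering.
#' @param fs_out Analysis sampling rate, Hz.
#' @return A marker-based angle series tibble at `fs_out`.
#' @export
process_markers <- function(markers, filter = filter_spec(), fs_out = 30) {
  check_series(markers, "marker")
  if (!is.null(filter)) markers <- filter_series(markers, filter)
  if (abs(series_fs(markers) - fs_out) > 1e-9) {
    markers <- resample_series(markers, fs_out)
  }
  marker_angles(markers)
}

#' Run the full concurrent-validity pipeline on a simulated trial
#'
#' Convenience wrapper chaining [process_distances()],
#' [process_markers()] and [validate_trial()] on an `sts_trial` bundle.
#'
#' @param trial An `sts_trial` from [simulate_trial()].
#' @param geom Chair geometry used for the inversion; defaults to the one
#'   the trial was simulated with.
#' @param filter A [filter_spec()] applied to both routes, or `NULL`.
#' @param ... Passed to [validate_trial()].
#' @return An `sts_validation` object.
#' @examples
#' trial <- simulate_trial("normal", seed = 42)
#' glance(analyze_trial(trial))
#' @export
analyze_trial <- function(trial, geom = trial$geom, filter = filter_spec(),
                          ...) {
  if (!inherits(trial, "sts_trial")) abort("`trial` must be an sts_trial")
  chair <- process_distances(trial$distances, geom, filter = filter)
  ref <- process_markers(trial$markers, filter = filter,
                         fs_out = series_fs(trial$distances))
  validate_trial(chair, ref, ...)
}
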