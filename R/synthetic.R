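#' Movement-condition presets
#'
#' Seven built-in sit-to-stand movement conditions: normal comfortable
#' motion, increased and decreased trunk anterior tilt, slow and fast
#' speed, and right/left weight shift. Each preset fixes the programmed
#' trunk flexion amplitude, extension overshoot past vertical, total
#' movement duration and thigh rise; the weight-shift conditions carry an
#' `asymmetry_gain` of +1/-1 which skews the flexion/extension timing split
#' and scales the optional in-plane thigh-distance offset of
#' [perturbation_spec()] (a sagittal model cannot represent a lateral
#' shift directly; this is its in-plane signature).
#'
#' Magnitudes are configurable package defaults representing typical adult
#' STS kinematics, not measured values.
#'
#' @param label One of `r paste0('"', sts_conditions(), '"', collapse = ", ")`.
#' @param ... Named overrides of preset fields (`flexion_amplitude_deg`,
#'   `extension_overshoot_deg`, `duration_s`, `thigh_rise_deg`,
#'   `thigh_baseline_deg`, `asymmetry_gain`).
#' @return A `condition_preset` object (named list).
#' @examples
#' condition_preset("tilt_increase")
#' @export
condition_preset <- function(label = sts_conditions(), ...) {
  label <- match.arg(label)
  base <- list(
    normal             = list(flexion_amplitude_deg = 50, duration_s = 2.0, asymmetry_gain = 0),
    tilt_increase      = list(flexion_amplitude_deg = 70, duration_s = 2.0, asymmetry_gain = 0),
    tilt_decrease      = list(flexion_amplitude_deg = 30, duration_s = 2.0, asymmetry_gain = 0),
    slow               = list(flexion_amplitude_deg = 50, duration_s = 4.0, asymmetry_gain = 0),
    fast               = list(flexion_amplitude_deg = 50, duration_s = 1.0, asymmetry_gain = 0),
    weight_shift_right = list(flexion_amplitude_deg = 50, duration_s = 2.2, asymmetry_gain = 1),
    weight_shift_left  = list(flexion_amplitude_deg = 50, duration_s = 2.2, asymmetry_gain = -1)
  )[[label]]
  preset <- utils::modifyList(
    c(list(label = label, extension_overshoot_deg = 5, thigh_rise_deg = 90,
           thigh_baseline_deg = 8), base),
    list(...)
  )
  if (preset$flexion_amplitude_deg <= 0) abort("flexion amplitude must be positive")
  if (preset$duration_s <= 0) abort("duration must be positive")
  structure(preset, class = "condition_preset")
}

#' @rdname condition_preset
#' @export
sts_conditions <- function() {
  c("normal", "tilt_increase", "tilt_decrease", "slow", "fast",
    "weight_shift_right", "weight_shift_left")
}

as_condition_preset <- function(preset) {
  if (inherits(preset, "condition_preset")) return(preset)
  if (is.character(preset) && length(preset) == 1L) return(condition_preset(preset))
  abort("`preset` must be a condition label or a condition_preset()")
}

#' Model-violation and noise terms for the virtual sensors
#'
#' All terms default to zero, i.e. the two-link model's assumptions hold
#' exactly and the virtual sensors are noise-free.
#'
#' @param surface_offset_mm Body-surface (clothing/tissue) thickness:
#'   subtracted from every ray-cast distance along the beam, so the sensor
#'   reads the surface, not the model line.
#' @param knee_shift_mm Posterior knee-axis translation, mm, ramped linearly
#'   from zero at peak trunk flexion to its full value at the end of the
#'   extension phase; the whole two-link origin translates with it. This is
#'   the mechanism by which a fixed assumed knee position inflates
#'   extension-phase trunk error.
#' @param distance_noise_sd_mm Gaussian noise SD added to each virtual
#'   laser distance sample.
#' @param marker_noise_sd_mm Gaussian noise SD added to each virtual marker
#'   coordinate.
#' @param thigh_offset_mm Additive in-plane thigh-distance offset, applied
#'   scaled by the preset's `asymmetry_gain` (weight-shift signature).
#' @param seed Optional default seed used by [simulate_trial()].
#' @return A `perturbation_spec` object.
#' @export
perturbation_spec <- function(surface_offset_mm = 0, knee_shift_mm = 0,
                              distance_noise_sd_mm = 0,
                              marker_noise_sd_mm = 0,
                              thigh_offset_mm = 0, seed = NULL) {
  if (distance_noise_sd_mm < 0 || marker_noise_sd_mm < 0) {
    abort("noise standard deviations must be non-negative")
  }
  structure(list(surface_offset_mm = surface_offset_mm,
                 knee_shift_mm = knee_shift_mm,
                 distance_noise_sd_mm = distance_noise_sd_mm,
                 marker_noise_sd_mm = marker_noise_sd_mm,
                 thigh_offset_mm = thigh_offset_mm,
                 seed = seed),
            class = "perturbation_spec")
}

# minimum-jerk position profile on [0, 1]
min_jerk <- function(u) {
  u <- pmin(1, pmax(0, u))
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Generate a ground-truth STS trajectory
#'
#' Trunk angle: quiet sitting at 0 for 0.5 s, minimum-jerk flexion to the
#' programmed amplitude, then minimum-jerk extension down to minus the
#' overshoot, then a 0.5 s standing hold. Thigh angle: holds the seated
#' baseline until peak trunk flexion, then a minimum-jerk rise to
#' `thigh_rise_deg` synchronised with the trunk extension phase (seat-off
#' to upright). Minimum-jerk profiles have zero velocity and acceleration
#' at both ends, matching smooth human point-to-point movement. The
#' flexion share of the movement duration is `0.45 + 0.03 * asymmetry_gain`.
#'
#' With a seed, the programmed amplitude and duration receive a uniform
#' per-trial jitter of up to `jitter_frac` (default 5%), emulating
#' trial-to-trial variability; the realised values and event times are
#' attached as the `events` attribute.
#'
#' @param preset A [condition_preset()] or condition label.
#' @param fs Sampling rate, Hz (>= 30).
#' @param seed Optional integer seed for the jitter draw.
#' @param jitter_frac Relative half-width of the amplitude/duration jitter.
#' @return A ground-truth angle series tibble with attribute `events`
#'   (list: `onset_s`, `peak_s`, `end_s`, `amplitude_deg`,
#'   `overshoot_deg`, `duration_s`).
#' @export
generate_trajectory <- function(preset = "normal", fs = 30, seed = NULL,
                                jitter_frac = 0.05) {
  preset <- as_condition_preset(preset)
  if (fs < 30) abort("`fs` must be at least 30 Hz")
  if (!is.null(seed)) set.seed(as.integer(seed))
  jit <- if (jitter_frac > 0) runif(2, 1 - jitter_frac, 1 + jitter_frac) else c(1, 1)
  amp <- preset$flexion_amplitude_deg * jit[1]
  dur <- preset$duration_s * jit[2]
  over <- preset$extension_overshoot_deg
  base_th <- preset$thigh_baseline_deg
  rise <- preset$thigh_rise_deg

  t0 <- 0.5
  f_frac <- 0.45 + 0.03 * preset$asymmetry_gain
  t1 <- t0 + f_frac * dur
  t2 <- t0 + dur
  t_end <- t2 + 0.5
  t <- seq(0, t_end, by = 1 / fs)

  trunk <- numeric(length(t))
  flex <- t >= t0 & t < t1
  ext <- t >= t1 & t <= t2
  trunk[flex] <- amp * min_jerk((t[flex] - t0) / (t1 - t0))
  trunk[ext] <- amp - (amp + over) * min_jerk((t[ext] - t1) / (t2 - t1))
  trunk[t > t2] <- -over

  thigh <- rep(base_th, length(t))
  thigh[ext] <- base_th + (rise - base_th) * min_jerk((t[ext] - t1) / (t2 - t1))
  thigh[t > t2] <- rise

  out <- tibble(
    t = t, theta_trunk_deg = trunk, theta_thigh_deg = thigh,
    source = "ground-truth", valid = TRUE
  )
  attr(out, "events") <- list(
    onset_s = t0, peak_s = t1, end_s = t2,
    amplitude_deg = amp, overshoot_deg = over, duration_s = dur
  )
  attr(out, "preset") <- preset$label
  out
}

# knee-axis posterior translation at time t: linear ramp over the
# extension phase (zero before peak flexion, full value from trial end)
knee_shift_at <- function(t, events, shift_mm) {
  if (shift_mm == 0) return(rep(0, length(t)))
  shift_mm * pmin(1, pmax(0, (t - events$peak_s) / (events$end_s - events$peak_s)))
}

#' Virtual seat-sensor distance by exact ray-casting
#'
#' Casts the seat-sensor beam (origin `(l_s1 + l_offset, 0)`, direction
#' `(-cos(phi_s1), sin(phi_s1))`) against the thigh segment from the
#' (possibly posteriorly shifted) knee to the hip, and returns the
#' intersection distance along the beam, minus the body-surface offset,
#' plus Gaussian noise if specified. Misses (thigh out of the beam, or hit
#' behind the sensor) return `NA`.
#'
#' @param theta_thigh True thigh angle(s), degrees.
#' @param geom A [chair_geometry()].
#' @param perturb A [perturbation_spec()].
#' @param knee_shift_mm Posterior knee translation per sample, mm (vector
#'   or scalar); defaults to the spec's static value.
#' @param body_thigh_mm The simulated subject's actual thigh length, mm
#'   (defaults to the model length, i.e. the assumption holds).
#' @return Distance(s) in mm, `NA` where the beam misses.
#' @export
forward_distance_thigh <- function(theta_thigh, geom = chair_geometry(),
                                   perturb = perturbation_spec(),
                                   knee_shift_mm = perturb$knee_shift_mm,
                                   body_thigh_mm = geom$l_thigh) {
  stopifnot_geometry(geom)
  th <- deg2rad(theta_thigh)
  phi <- deg2rad(geom$phi_s1)
  A <- geom$l_s1 + geom$l_offset
  k <- rep_len(knee_shift_mm, length(th))
  det <- sin(th + phi)  # times body_thigh_mm; sign is what matters
  s <- (A - k) * sin(th) / det
  w <- (A - k) * sin(phi) / (body_thigh_mm * det)
  miss <- is.na(s) | abs(det) < 1e-12 | s <= 0 | w < 0 | w > 1
  d <- s - perturb$surface_offset_mm
  if (perturb$distance_noise_sd_mm > 0) {
    d <- d + rnorm(length(d), 0, perturb$distance_noise_sd_mm)
  }
  d[miss] <- NA_real_
  d
}

#' Virtual backrest-sensor distance by exact ray-casting
#'
#' Casts the backrest beam (origin `(l_seat, l_s2)`, direction
#' `(-sin(phi_s2), -cos(phi_s2))`) against the trunk, modelled as a
#' half-line rising from the hip at `theta_trunk` from vertical (hits above
#' the C7 level are accepted as neck/head returns; hits at or below the hip
#' are misses). The hip follows the true thigh angle and the (possibly
#' shifted) knee. Surface offset and noise as in
#' [forward_distance_thigh()].
#'
#' @param theta_trunk True trunk angle(s), degrees from vertical.
#' @inheritParams forward_distance_thigh
#' @return Distance(s) in mm, `NA` where the beam misses.
#' @export
forward_distance_trunk <- function(theta_trunk, theta_thigh,
                                   geom = chair_geometry(),
                                   perturb = perturbation_spec(),
                                   knee_shift_mm = perturb$knee_shift_mm,
                                   body_thigh_mm = geom$l_thigh) {
  stopifnot_geometry(geom)
  tr <- deg2rad(theta_trunk)
  th <- deg2rad(theta_thigh)
  phi <- deg2rad(geom$phi_s2)
  k <- rep_len(knee_shift_mm, length(tr))
  hip_x <- k + body_thigh_mm * cos(th)
  hip_y <- body_thigh_mm * sin(th)
  det <- sin(phi + tr)
  s <- ((geom$l_seat - hip_x) * cos(tr) + (geom$l_s2 - hip_y) * sin(tr)) / det
  u <- (sin(phi) * (geom$l_s2 - hip_y) - cos(phi) * (geom$l_seat - hip_x)) / det
  miss <- is.na(s) | abs(det) < 1e-12 | s <= 0 | u <= 0
  d <- s - perturb$surface_offset_mm
  if (perturb$distance_noise_sd_mm > 0) {
    d <- d + rnorm(length(d), 0, perturb$distance_noise_sd_mm)
  }
  d[miss] <- NA_real_
  d
}

#' Virtual marker trajectories from a ground-truth trajectory
#'
#' Places the four sagittal landmarks on the true two-link pose: the
#' lateral femoral condyle at the (possibly shifted) knee centre, the
#' greater trochanter at the hip, the sacrum a fixed offset above the hip
#' along the trunk line, and C7 a trunk length above the sacrum. Isotropic
#' Gaussian noise is added per coordinate if specified. Because markers
#' track the actual body, knee-axis translation moves the marker positions
#' but leaves marker-derived segment *angles* untouched.
#'
#' @param truth Ground-truth angle series from [generate_trajectory()]
#'   (carrying its `events` attribute), at or resampled to `fs_out`.
#' @inheritParams forward_distance_thigh
#' @param trunk_length_mm Sacrum-to-C7 distance, mm.
#' @param sacrum_offset_mm Hip-to-sacrum distance along the trunk line, mm.
#' @param fs_out Output sampling rate, Hz.
#' @return A marker series tibble (see [series]).
#' @export
simulate_markers <- function(truth, geom = chair_geometry(),
                             perturb = perturbation_spec(),
                             body_thigh_mm = geom$l_thigh,
                             trunk_length_mm = 500, sacrum_offset_mm = 80,
                             fs_out = 100) {
  check_series(truth, "angle")
  events <- attr(truth, "events")
  if (abs(series_fs(truth) - fs_out) > 1e-6) {
    truth <- resample_series(truth, fs_out)
  }
  th <- deg2rad(truth$theta_thigh_deg)
  tr <- deg2rad(truth$theta_trunk_deg)
  k <- if (is.null(events)) rep(0, nrow(truth)) else {
    knee_shift_at(truth$t, events, perturb$knee_shift_mm)
  }
  hip_x <- k + body_thigh_mm * cos(th)
  hip_y <- body_thigh_mm * sin(th)
  tdir_x <- -sin(tr)
  tdir_y <- cos(tr)
  out <- tibble(
    t = truth$t,
    c7_x_mm = hip_x + (sacrum_offset_mm + trunk_length_mm) * tdir_x,
    c7_y_mm = hip_y + (sacrum_offset_mm + trunk_length_mm) * tdir_y,
    sacrum_x_mm = hip_x + sacrum_offset_mm * tdir_x,
    sacrum_y_mm = hip_y + sacrum_offset_mm * tdir_y,
    trochanter_x_mm = hip_x,
    trochanter_y_mm = hip_y,
    condyle_x_mm = k,
    condyle_y_mm = rep(0, nrow(truth))
  )
  if (perturb$marker_noise_sd_mm > 0) {
    for (col in setdiff(names(out), "t")) {
      out[[col]] <- out[[col]] + rnorm(nrow(out), 0, perturb$marker_noise_sd_mm)
    }
  }
  out
}

#' Segment angles from marker trajectories
#'
#' Trunk angle: signed angle of the sacrum-to-C7 line from vertical,
#' flexion (forward lean) positive. Thigh angle: signed angle of the
#' condyle-to-trochanter line from horizontal. Frames with coincident
#' markers are flagged invalid.
#'
#' @param markers A marker series tibble (see [series]).
#' @return An angle series tibble with `source = "marker-based"`.
#' @export
marker_angles <- function(markers) {
  check_series(markers, "marker")
  vx_tr <- markers$c7_x_mm - markers$sacrum_x_mm
  vy_tr <- markers$c7_y_mm - markers$sacrum_y_mm
  vx_th <- markers$trochanter_x_mm - markers$condyle_x_mm
  vy_th <- markers$trochanter_y_mm - markers$condyle_y_mm
  bad <- (vx_tr^2 + vy_tr^2 < 1e-12) | (vx_th^2 + vy_th^2 < 1e-12)
  # x is posterior-positive, so forward lean = negative x component
  trunk <- rad2deg(atan2(-vx_tr, vy_tr))
  thigh <- rad2deg(atan2(vy_th, vx_th))
  trunk[bad] <- NA_real_
  thigh[bad] <- NA_real_
  tibble(
    t = markers$t,
    theta_trunk_deg = trunk,
    theta_thigh_deg = thigh,
    source = "marker-based",
    valid = !bad
  )
}

#' Simulate a complete virtual STS trial
#'
#' Bundles the generator and both virtual sensing routes: a ground-truth
#' trajectory (with per-trial jitter drawn from `seed`), the virtual laser
#' distances at `fs_distance` and the virtual marker trajectories at
#' `fs_marker`, under a shared [perturbation_spec()]. Fully reproducible
#' from `seed`.
#'
#' @inheritParams generate_trajectory
#' @inheritParams simulate_markers
#' @param fs_distance Laser sampling rate, Hz.
#' @param fs_marker Marker sampling rate, Hz.
#' @return An object of class `sts_trial`: list with `distances` (distance
#'   series), `markers` (marker series), `truth` (ground-truth angle series
#'   at `fs_distance`), `events` (one-row tibble of true event times),
#'   `true_excursions` (one-row tibble), plus the `preset`, `perturb`,
#'   `geom` and `seed` that produced it.
#' @examples
#' trial <- simulate_trial("normal", seed = 1)
#' trial$events
#' @export
simulate_trial <- function(preset = "normal", geom = chair_geometry(),
                           perturb = perturbation_spec(),
                           seed = perturb$seed, fs_distance = 30,
                           fs_marker = 100, jitter_frac = 0.05,
                           body_thigh_mm = geom$l_thigh,
                           trunk_length_mm = 500, sacrum_offset_mm = 80) {
  preset <- as_condition_preset(preset)
  truth <- generate_trajectory(preset, fs = fs_distance, seed = seed,
                               jitter_frac = jitter_frac)
  truth_hi <- generate_trajectory(preset, fs = fs_marker, seed = seed,
                                  jitter_frac = jitter_frac)
  events <- attr(truth, "events")
  if (!is.null(seed)) {
    set.seed(as.integer((abs(as.numeric(seed)) + 500007) %% 2147483647))
  }
  k <- knee_shift_at(truth$t, events, perturb$knee_shift_mm)
  d_thigh <- forward_distance_thigh(truth$theta_thigh_deg, geom, perturb,
                                    knee_shift_mm = k,
                                    body_thigh_mm = body_thigh_mm)
  d_thigh <- d_thigh + preset$asymmetry_gain * perturb$thigh_offset_mm
  d_trunk <- forward_distance_trunk(truth$theta_trunk_deg,
                                    truth$theta_thigh_deg, geom, perturb,
                                    knee_shift_mm = k,
                                    body_thigh_mm = body_thigh_mm)
  valid <- !is.na(d_thigh) & !is.na(d_trunk) &
    d_thigh > 0 & d_thigh <= geom$sensor_max_range &
    d_trunk > 0 & d_trunk <= geom$sensor_max_range
  distances <- tibble(t = truth$t, d_thigh_mm = d_thigh,
                      d_trunk_mm = d_trunk, valid = valid)
  markers <- simulate_markers(truth_hi, geom, perturb,
                              body_thigh_mm = body_thigh_mm,
                              trunk_length_mm = trunk_length_mm,
                              sacrum_offset_mm = sacrum_offset_mm,
                              fs_out = fs_marker)
  structure(
    list(
      distances = distances,
      markers = markers,
      truth = truth,
      events = tibble(onset_s = events$onset_s, peak_s = events$peak_s,
                      end_s = events$end_s),
      true_excursions = tibble(
        flexion_deg = events$amplitude_deg,
        extension_deg = events$amplitude_deg + events$overshoot_deg
      ),
      preset = preset,
      perturb = perturb,
      geom = geom,
      seed = seed
    ),
    class = "sts_trial"
  )
}

#' @export
print.sts_trial <- function(x, ...) {
  cat("<sts_trial>\n")
  cat(sprintf("  condition : %s (seed %s)\n", x$preset$label,
              x$seed %||% "none"))
  cat(sprintf("  distances : %d samples @ %.0f Hz | markers: %d samples @ %.0f Hz\n",
              nrow(x$distances), series_fs(x$distances),
              nrow(x$markers), series_fs(x$markers)))
  cat(sprintf("  events    : onset %.2f s, peak flexion %.2f s, end %.2f s\n",
              x$events$onset_s, x$events$peak_s, x$events$end_s))
  invisible(x)
}
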