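#' Chair and sensor geometry of the two-link model
#'
#' Bundles every fixed length and installation angle of the instrumented
#' chair. The sagittal-plane frame has its origin at the knee joint centre,
#' x positive toward the backrest (posterior) and y positive upward from the
#' seat plane; the backrest plane is at `x = l_seat` and the seat plane at
#' `y = 0`. The seat sensor sits at `(l_s1 + l_offset, 0)` with its beam
#' directed `(-cos(phi_s1), +sin(phi_s1))`; the backrest sensor sits at
#' `(l_seat, l_s2)` with beam `(-sin(phi_s2), -cos(phi_s2))`. In this frame
#' the three inverse-geometry relations implemented by
#' [thigh_angle_from_distance()], [hip_position()] and
#' [trunk_angle_from_distance()] are exact identities of the forward
#' ray-cast model in [forward_distance_thigh()] / [forward_distance_trunk()].
#'
#' Defaults are the reference chair: seat sensor at 63.5 degrees, 130 mm
#' behind the seat edge with a 50 mm edge-to-knee offset; backrest sensor
#' perpendicular (90 degrees) at 465 mm above a 550 mm deep, 400 mm high
#' seat; model thigh length 403 mm (the 446 mm alternative matches taller
#' users).
#'
#' @param phi_s1 Seat-sensor installation angle, degrees from the seat plane.
#' @param l_s1 Seat-sensor to seat-edge length, mm.
#' @param l_offset Seat-edge to knee-centre length along the seat plane, mm.
#' @param phi_s2 Backrest-sensor installation angle, degrees from the
#'   backrest plane (90 = beam parallel to the seat).
#' @param l_seat Seat depth (knee centre to backrest plane), mm.
#' @param l_s2 Backrest-sensor height above the seat plane, mm.
#' @param l_thigh Model thigh length, mm (403 or 446 in the reference setup).
#' @param seat_height Seat height above the floor, mm (metadata only; no
#'   kinematic role).
#' @param sensor_max_range Maximum usable sensor range, mm; longer readings
#'   are flagged invalid.
#' @return An object of class `chair_geometry` (named list).
#' @examples
#' geom <- chair_geometry()
#' thigh_angle_from_distance(100, geom)
#' @export
chair_geometry <- function(phi_s1 = 63.5, l_s1 = 130, l_offset = 50,
                           phi_s2 = 90, l_seat = 550, l_s2 = 465,
                           l_thigh = 403, seat_height = 400,
                           sensor_max_range = 2000) {
  geom <- list(
    phi_s1 = phi_s1, l_s1 = l_s1, l_offset = l_offset,
    phi_s2 = phi_s2, l_seat = l_seat, l_s2 = l_s2,
    l_thigh = l_thigh, seat_height = seat_height,
    sensor_max_range = sensor_max_range
  )
  lens <- c("l_s1", "l_offset", "l_seat", "l_s2", "l_thigh", "seat_height",
            "sensor_max_range")
  for (nm in names(geom)) {
    v <- geom[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("chair_geometry: `%s` must be a finite scalar", nm))
    }
  }
  if (any(unlist(geom[lens]) <= 0)) {
    abort("chair_geometry: all lengths must be positive")
  }
  if (phi_s1 <= 0 || phi_s1 >= 180) {
    abort("chair_geometry: phi_s1 must lie in (0, 180) degrees")
  }
  if (phi_s2 <= 0 || phi_s2 > 180) {
    abort("chair_geometry: phi_s2 must lie in (0, 180] degrees")
  }
  structure(geom, class = "chair_geometry")
}

#' @export
print.chair_geometry <- function(x, ...) {
  cat("<chair_geometry>\n")
  cat(sprintf("  seat sensor : phi_s1 = %g deg, l_s1 = %g mm, l_offset = %g mm\n",
              x$phi_s1, x$l_s1, x$l_offset))
  cat(sprintf("  back sensor : phi_s2 = %g deg, l_seat = %g mm, l_s2 = %g mm\n",
              x$phi_s2, x$l_seat, x$l_s2))
  cat(sprintf("  model       : l_thigh = %g mm, seat_height = %g mm, max range = %g mm\n",
              x$l_thigh, x$seat_height, x$sensor_max_range))
  invisible(x)
}

stopifnot_geometry <- function(geom) {
  if (!inherits(geom, "chair_geometry")) {
    abort("`geom` must be a chair_geometry object (see chair_geometry())")
  }
  geom
}

#' Thigh angle from the seat-sensor distance
#'
#' Inverts the seat-beam geometry: the beam leaves the seat sensor at
#' `phi_s1` and meets the thigh line through the knee at distance `d_thigh`,
#' giving the thigh elevation
#' `theta = atan(d*sin(phi_s1) / ((l_s1 + l_offset) - d*cos(phi_s1)))`.
#'
#' A non-positive denominator means the beam's hit point lies at or beyond
#' the knee plane, where the model is undefined: for vector input the sample
#' is returned as `NA` (to be carried as an invalid flag); a scalar input is
#' a domain error.
#'
#' @param d_thigh Seat-sensor distance(s), mm; must be positive.
#' @param geom A [chair_geometry()].
#' @return Thigh angle(s) in degrees from horizontal (0 = seated thigh).
#' @export
thigh_angle_from_distance <- function(d_thigh, geom = chair_geometry()) {
  stopifnot_geometry(geom)
  if (length(d_thigh) == 0L) abort("`d_thigh` is empty")
  if (any(!is.na(d_thigh) & d_thigh <= 0)) {
    abort("`d_thigh` must be positive (distance in mm)")
  }
  phi <- deg2rad(geom$phi_s1)
  den <- (geom$l_s1 + geom$l_offset) - d_thigh * cos(phi)
  num <- d_thigh * sin(phi)
  bad <- !is.na(den) & den <= 0
  if (length(d_thigh) == 1L && bad) {
    abort("thigh beam hit point at or beyond the knee plane (denominator <= 0)")
  }
  out <- rad2deg(atan(num / den))
  out[bad] <- NA_real_
  out
}

#' Hip position implied by the thigh angle
#'
#' Places the hip on a circle of radius `l_thigh` about the knee:
#' `x = l_thigh*cos(theta)`, `y = l_thigh*sin(theta)` in the knee-origin
#' frame (x posterior, y up).
#'
#' @param theta_thigh Thigh angle(s), degrees; must lie in (-90, 90).
#'   `NA` values propagate.
#' @param geom A [chair_geometry()].
#' @return A tibble with columns `x`, `y` (mm), one row per input angle.
#' @export
hip_position <- function(theta_thigh, geom = chair_geometry()) {
  stopifnot_geometry(geom)
  ok <- is.na(theta_thigh) | (theta_thigh > -90 & theta_thigh < 90)
  if (!all(ok)) {
    abort("`theta_thigh` must lie strictly inside (-90, 90) degrees")
  }
  th <- deg2rad(theta_thigh)
  tibble(x = geom$l_thigh * cos(th), y = geom$l_thigh * sin(th))
}

#' Trunk angle from the backrest-sensor distance
#'
#' Inverts the backrest-beam geometry given the hip position: the beam's hit
#' point on the trunk is `(l_seat - d*sin(phi_s2), l_s2 - d*cos(phi_s2))`,
#' and the trunk angle from vertical (flexion positive, i.e. forward lean) is
#' `atan((d*sin(phi_s2) - (l_seat - x_hip)) / (l_s2 - d*cos(phi_s2) - y_hip))`.
#'
#' A non-positive denominator means the beam met the trunk at or below hip
#' height, where the model is undefined: `NA` for vector input, a domain
#' error for scalar input.
#'
#' @param d_trunk Backrest-sensor distance(s), mm; positive.
#' @param hip Hip position: a data frame with columns `x`, `y` (as returned
#'   by [hip_position()]) or a length-2 numeric `c(x, y)`, mm.
#' @param geom A [chair_geometry()].
#' @return Trunk angle(s) in degrees from vertical, flexion positive.
#' @export
trunk_angle_from_distance <- function(d_trunk, hip, geom = chair_geometry()) {
  stopifnot_geometry(geom)
  if (is.numeric(hip) && length(hip) == 2L) {
    hip <- tibble(x = hip[[1]], y = hip[[2]])
  }
  if (!is.data.frame(hip) || !all(c("x", "y") %in% names(hip))) {
    abort("`hip` must be a data frame with columns x, y or a length-2 numeric")
  }
  if (length(d_trunk) == 0L) abort("`d_trunk` is empty")
  if (any(!is.na(d_trunk) & d_trunk <= 0)) {
    abort("`d_trunk` must be positive (distance in mm)")
  }
  phi <- deg2rad(geom$phi_s2)
  num <- d_trunk * sin(phi) - (geom$l_seat - hip$x)
  den <- geom$l_s2 - d_trunk * cos(phi) - hip$y
  bad <- !is.na(den) & den <= 0
  if (length(d_trunk) == 1L && nrow(hip) == 1L && bad) {
    abort("trunk beam hit point at or below hip height (denominator <= 0)")
  }
  out <- rad2deg(atan(num / den))
  out[bad] <- NA_real_
  out
}

#' Convert a distance series to chair-model segment angles
#'
#' Vectorised composition of the two-link inversion over a whole trial:
#' thigh angle from `d_thigh_mm`, hip position from the thigh angle, trunk
#' angle from `d_trunk_mm` and the hip. Samples whose distances are missing,
#' non-positive, beyond `sensor_max_range`, or whose inversion denominators
#' are non-positive, are flagged invalid (`valid = FALSE`, angles `NA`);
#' valid angles outside the physically meaningful bands (thigh
#' `[-10, 100]`, trunk `[-90, 120]` degrees) are likewise flagged.
#'
#' @param distances A distance series: data frame with columns `t` (s),
#'   `d_thigh_mm`, `d_trunk_mm` and optionally `valid`.
#' @param geom A [chair_geometry()].
#' @return An angle series tibble with columns `t`, `theta_trunk_deg`,
#'   `theta_thigh_deg`, `source = "chair-model"`, `valid`.
#' @examples
#' d <- tibble::tibble(t = 0:9 / 30, d_thigh_mm = 100, d_trunk_mm = 250)
#' sts_angles(d, chair_geometry())
#' @export
sts_angles <- function(distances, geom = chair_geometry()) {
  stopifnot_geometry(geom)
  check_series(distances, kind = "distance")
  if (nrow(distances) == 0L) abort("`distances` is empty")
  valid_in <- if ("valid" %in% names(distances)) {
    as.logical(distances$valid)
  } else {
    rep(TRUE, nrow(distances))
  }
  dth <- distances$d_thigh_mm
  dtr <- distances$d_trunk_mm
  in_range <- function(d) !is.na(d) & d > 0 & d <= geom$sensor_max_range
  ok <- valid_in & in_range(dth) & in_range(dtr)

  theta_thigh <- rep(NA_real_, nrow(distances))
  theta_trunk <- rep(NA_real_, nrow(distances))
  if (any(ok)) {
    th <- thigh_angle_from_distance(dth[ok], geom)
    hip <- hip_position(th, geom)
    tr <- trunk_angle_from_distance(dtr[ok], hip, geom)
    theta_thigh[ok] <- th
    theta_trunk[ok] <- tr
  }
  valid <- ok & !is.na(theta_thigh) & !is.na(theta_trunk) &
    theta_thigh >= -10 & theta_thigh <= 100 &
    theta_trunk >= -90 & theta_trunk <= 120
  theta_thigh[!valid] <- NA_real_
  theta_trunk[!valid] <- NA_real_
  tibble(
    t = distances$t,
    theta_trunk_deg = theta_trunk,
    theta_thigh_deg = theta_thigh,
    source = "chair-model",
    valid = valid
  )
}

#' Read / write a chair geometry config file
#'
#' Flat `key = value` text format with exactly the keys `phi_s1, l_s1,
#' l_offset, phi_s2, l_seat, l_s2, l_thigh, seat_height, sensor_max_range`.
#' Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_chair_geometry()` returns a [chair_geometry()];
#'   `write_chair_geometry()` returns `path` invisibly.
#' @export
read_chair_geometry <- function(path) {
  if (!file.exists(path)) abort(sprintf("geometry config not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    abort("geometry config must contain `key = value` lines")
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2L))))
  if (anyNA(vals)) abort("geometry config contains non-numeric values")
  args <- as.list(setNames(vals, keys))
  allowed <- names(formals(chair_geometry))
  unknown <- setdiff(keys, allowed)
  if (length(unknown)) {
    abort(sprintf("unknown geometry keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(chair_geometry, args)
}

#' @param geom A [chair_geometry()] to serialise.
#' @rdname read_chair_geometry
#' @export
write_chair_geometry <- function(geom, path) {
  stopifnot_geometry(geom)
  lines <- c(
    "# chairsts chair geometry (mm, degrees)",
    sprintf("%s = %.10g", names(unclass(geom)), unlist(geom))
  )
  writeLines(lines, path)
  invisible(path)
}
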