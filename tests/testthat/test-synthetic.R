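test_that("trajectories follow the programmed minimum-jerk profile", {
  tr <- generate_trajectory("normal", fs = 30, seed = 4)
  ev <- attr(tr, "events")
  # peak equals the (jittered) programmed amplitude, at the programmed time
  expect_equal(max(tr$theta_trunk_deg), ev$amplitude_deg, tolerance = 0.01)
  expect_lte(abs(ev$amplitude_deg / 50 - 1), 0.05)   # jitter bound
  expect_lte(abs(ev$duration_s / 2.0 - 1), 0.05)
  ipk <- which.max(tr$theta_trunk_deg)
  expect_lte(abs(tr$t[ipk] - ev$peak_s), 1 / 30)
  # quiet sitting before onset, standing hold at the end
  expect_equal(tr$theta_trunk_deg[tr$t < ev$onset_s], rep(0, sum(tr$t < ev$onset_s)))
  expect_equal(tail(tr$theta_trunk_deg, 1), -ev$overshoot_deg)
  expect_equal(tail(tr$theta_thigh_deg, 1), 90)

  # minimum-jerk boundary conditions: vanishing endpoint velocity
  hi <- generate_trajectory("normal", fs = 3000, seed = 4)
  v <- diff(hi$theta_trunk_deg) * 3000
  ev2 <- attr(hi, "events")
  at <- function(s) which.min(abs(hi$t[-1] - s))
  expect_lt(abs(v[at(ev2$onset_s) + 1]), 0.01)
  expect_lt(abs(v[at(ev2$end_s) - 1]), 0.01)
})

test_that("slow and fast presets trace the same path at scaled duration", {
  # jitter disabled: fast at 120 Hz and slow at 30 Hz sample the same
  # movement fractions (1 s * 120 = 4 s * 30 samples)
  fast <- generate_trajectory("fast", fs = 120, seed = NULL, jitter_frac = 0)
  slow <- generate_trajectory("slow", fs = 30, seed = NULL, jitter_frac = 0)
  ef <- attr(fast, "events")
  es <- attr(slow, "events")
  expect_equal(es$duration_s / ef$duration_s, 4)
  wf <- fast$t >= ef$onset_s & fast$t <= ef$end_s
  ws <- slow$t >= es$onset_s & slow$t <= es$end_s
  expect_equal(fast$theta_trunk_deg[wf], slow$theta_trunk_deg[ws],
               tolerance = 1e-9)
})

test_that("forward distances invert exactly and match hand-derived cases", {
  geom <- chair_geometry()
  # inverse of the 33.4668 deg worked example
  d <- forward_distance_thigh(33.466798, geom)
  expect_equal(d, 100, tolerance = 1e-4)
  # d(45 deg) = 180 sin45 / sin(108.5) on an independent calculator
  expect_equal(forward_distance_thigh(45, geom), 134.214959, tolerance = 1e-6)
  expect_equal(thigh_angle_from_distance(forward_distance_thigh(45, geom), geom),
               45, tolerance = 1e-9)
  # upright trunk over seated thigh: L_seat - L_thigh
  expect_equal(forward_distance_trunk(0, 0, geom), 147, tolerance = 1e-9)
  # trunk round trip at an arbitrary pose
  d2 <- forward_distance_trunk(30, 20, geom)
  hip <- hip_position(20, geom)
  expect_equal(trunk_angle_from_distance(d2, hip, geom), 30, tolerance = 1e-9)
  # thigh out of the beam: miss is NA
  expect_true(is.na(forward_distance_thigh(-5, geom)))
})

test_that("surface offset biases the inversion; knee shift spares flexion", {
  geom <- chair_geometry()
  p20 <- perturbation_spec(surface_offset_mm = 20)
  d <- forward_distance_thigh(45, geom, p20)
  th_hat <- thigh_angle_from_distance(d, geom)
  expect_gt(abs(th_hat - 45), 0.5)

  # knee shift displaces the distance only where the ramp is active
  tr <- generate_trajectory("normal", fs = 30, seed = 2)
  ev <- attr(tr, "events")
  k <- 30 * pmin(1, pmax(0, (tr$t - ev$peak_s) / (ev$end_s - ev$peak_s)))
  d0 <- forward_distance_thigh(tr$theta_thigh_deg, geom)
  d1 <- forward_distance_thigh(tr$theta_thigh_deg, geom, knee_shift_mm = k)
  pre <- tr$t <= ev$peak_s
  expect_equal(d1[pre], d0[pre], tolerance = 1e-12)
  expect_gt(max(abs(d1[!pre] - d0[!pre]), na.rm = TRUE), 1)
})

test_that("virtual markers reproduce the truth and stay rigid", {
  trial <- simulate_trial("normal", seed = 6)
  mk <- trial$markers
  ang <- marker_angles(mk)
  truth_hi <- generate_trajectory("normal", fs = 100, seed = 6)
  expect_equal(ang$theta_trunk_deg, truth_hi$theta_trunk_deg, tolerance = 1e-9)
  expect_equal(ang$theta_thigh_deg, truth_hi$theta_thigh_deg, tolerance = 1e-9)
  # rigid thigh: trochanter-condyle distance constant
  L <- sqrt((mk$trochanter_x_mm - mk$condyle_x_mm)^2 +
            (mk$trochanter_y_mm - mk$condyle_y_mm)^2)
  expect_lt(diff(range(L)), 1e-9)
  expect_equal(L[1], trial$geom$l_thigh, tolerance = 1e-9)
})

test_that("marker noise propagates to angles by the small-angle law", {
  # sd(theta) ~ sqrt(2) * sigma / L radians for 1 mm noise on 400 mm segments
  truth <- angle_series(seq(0, 30, by = 0.01), trunk = 20, thigh = 8)
  attr(truth, "events") <- NULL
  set.seed(31)
  mk <- simulate_markers(truth, chair_geometry(),
                         perturbation_spec(marker_noise_sd_mm = 1),
                         body_thigh_mm = 400, trunk_length_mm = 400,
                         sacrum_offset_mm = 80)
  ang <- marker_angles(mk)
  expect_equal(sd(ang$theta_trunk_deg), 0.202571, tolerance = 0.1)
  expect_equal(sd(ang$theta_thigh_deg), 0.202571, tolerance = 0.1)
})

test_that("marker angle conventions match their geometric definitions", {
  base <- tibble::tibble(
    t = c(0, 0.01, 0.02),
    c7_x_mm = 0, c7_y_mm = 500, sacrum_x_mm = 0, sacrum_y_mm = 0,
    trochanter_x_mm = 400, trochanter_y_mm = 0,
    condyle_x_mm = 0, condyle_y_mm = 0
  )
  a <- marker_angles(base)
  expect_equal(a$theta_trunk_deg, rep(0, 3))  # C7 directly above sacrum
  expect_equal(a$theta_thigh_deg, rep(0, 3))  # markers at equal height

  lean <- base
  lean$c7_x_mm <- -300  # anterior (toward the knee) and up: 45 deg flexion
  lean$c7_y_mm <- 300
  expect_equal(marker_angles(lean)$theta_trunk_deg, rep(45, 3))

  degenerate <- base
  degenerate$c7_x_mm[2] <- 0
  degenerate$c7_y_mm[2] <- 0  # C7 on the sacrum
  out <- marker_angles(degenerate)
  expect_equal(out$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(out$theta_trunk_deg[2]))
})

test_that("trials are reproducible from their seed and share noiseless cores", {
  t1 <- simulate_trial("normal", seed = 12,
                       perturb = perturbation_spec(distance_noise_sd_mm = 2))
  t2 <- simulate_trial("normal", seed = 12,
                       perturb = perturbation_spec(distance_noise_sd_mm = 2))
  expect_identical(t1$distances, t2$distances)
  expect_identical(t1$markers, t2$markers)

  # distinct seeds, jitter disabled: identical truth, distinct noise
  t3 <- simulate_trial("normal", seed = 1, jitter_frac = 0,
                       perturb = perturbation_spec(distance_noise_sd_mm = 2))
  t4 <- simulate_trial("normal", seed = 2, jitter_frac = 0,
                       perturb = perturbation_spec(distance_noise_sd_mm = 2))
  expect_equal(t3$truth, t4$truth)
  expect_gt(max(abs(t3$distances$d_thigh_mm - t4$distances$d_thigh_mm),
                na.rm = TRUE), 0.1)
})

test_that("every preset exists and yields a pipeline-clean noiseless trial", {
  expect_length(sts_conditions(), 7)
  for (cond in sts_conditions()) {
    trial <- simulate_trial(cond, seed = 3)
    expect_s3_class(trial, "sts_trial")
    v <- analyze_trial(trial, filter = NULL)
    g <- glance(v)
    expect_lt(g$abs_err_flexion_deg, 0.1)
    expect_lt(g$abs_err_extension_deg, 0.1)
  }
})
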