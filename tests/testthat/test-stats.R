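test_that("similarity and correlation match longhand formula oracles", {
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(10)
    b <- rnorm(10)
    expect_equal(waveform_similarity(a, b), pearson_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(across_trial_correlation(a, b), pearson_oracle(a, b),
                 tolerance = 1e-12)
    rs <- runif(10, -0.95, 0.95)
    expect_equal(fisher_mean(rs), fisher_oracle(rs), tolerance = 1e-12)
  }
})

test_that("waveform similarity identities and affine invariance hold", {
  a <- sin(seq(0, 2 * pi, length.out = 50))
  expect_equal(waveform_similarity(a, a), 1.0, tolerance = 1e-12)
  expect_equal(waveform_similarity(a, -a), -1.0, tolerance = 1e-12)
  b <- rnorm(50)
  r0 <- waveform_similarity(a, b)
  expect_equal(waveform_similarity(3.2 * a + 7, b), r0, tolerance = 1e-12)
  expect_equal(waveform_similarity(a, 0.5 * b - 2), r0, tolerance = 1e-12)
  expect_error(waveform_similarity(rep(1, 10), a[1:10]), "degenerate")
  expect_error(waveform_similarity(a[1:2], a[1:2]), "too short")
})

test_that("lag-search mode recovers similarity of a delayed waveform", {
  fs <- 30
  t <- seq(0, 3, by = 1 / fs)
  a <- sin(2 * pi * t)
  lagged <- sin(2 * pi * (t - 3 / fs))  # 3-sample delay (0.1 s)
  r0 <- waveform_similarity(a, lagged)
  rmax <- waveform_similarity(a, lagged, lag_mode = "max", fs = fs)
  expect_lt(r0, rmax)
  expect_gt(rmax, 0.9999)
  expect_error(waveform_similarity(a, lagged, lag_mode = "max"), "fs")
})

test_that("noisy-replica similarity matches the closed-form attenuation", {
  # b = a + noise with sd = 0.5 sd(a): r = 1/sqrt(1 + 0.25) = 0.8944
  set.seed(101)
  a <- sin(seq(0, 4 * pi, length.out = 120))
  rs <- replicate(400, {
    waveform_similarity(a, a + rnorm(length(a), 0, 0.5 * sd(a)))
  })
  expect_equal(mean(rs), 0.894427, tolerance = 0.03)
})

test_that("fisher averaging matches hand computations and stays bounded", {
  expect_equal(fisher_mean(c(0.5, 0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(fisher_mean(c(0.8, -0.8)), 0, tolerance = 1e-12)
  # tanh((atanh 0.9 + atanh 0.5)/2), independent evaluation
  expect_equal(fisher_mean(c(0.9, 0.5)), 0.7660773, tolerance = 1e-6)
  # bounded between min and max of its inputs
  set.seed(5)
  for (i in 1:10) {
    rs <- runif(6, -0.99, 0.99)
    fm <- fisher_mean(rs)
    expect_gte(fm, min(rs))
    expect_lte(fm, max(rs))
  }
  expect_warning(out <- fisher_mean(c(1, 0.5)), "clipped")
  expect_lt(out, 1)
  expect_error(fisher_mean(c(0.5, 1.2)), "lie in")
  expect_error(fisher_mean(numeric(0)), "non-empty")
})

test_that("excursion errors follow the absolute/percentage definitions", {
  mk <- function(f, e) tibble::tibble(flexion_deg = f, extension_deg = e)
  same <- excursion_errors(mk(40, 45), mk(40, 45))
  expect_equal(same$abs_err_deg, c(0, 0))
  expect_equal(same$pct_err, c(0, 0))

  err <- excursion_errors(mk(54.8, 45), mk(58.6, 45))
  expect_equal(err$abs_err_deg[err$phase == "flexion"], 3.8, tolerance = 1e-9)
  expect_equal(err$pct_err[err$phase == "flexion"], 6.484642, tolerance = 1e-5)

  zero_ref <- excursion_errors(mk(10, 5), mk(10, 0))
  expect_true(is.na(zero_ref$pct_err[zero_ref$phase == "extension"]))
  expect_equal(zero_ref$abs_err_deg[zero_ref$phase == "extension"], 5)
})

test_that("independent noise gives near-zero across-trial correlation", {
  set.seed(77)
  rs <- replicate(1000, across_trial_correlation(rnorm(35), rnorm(35)))
  expect_lt(abs(mean(rs)), 0.02)
  expect_error(across_trial_correlation(1:5, 2 * (1:5) + 1), NA)
  expect_equal(across_trial_correlation(1:5, 2 * (1:5) + 1), 1, tolerance = 1e-12)
  expect_error(across_trial_correlation(1:4, 1:5), "equal length")
  expect_error(across_trial_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("condition summaries Fisher-average correlations and average errors", {
  trials <- tibble::tibble(
    condition = rep(c("normal", "fast"), each = 3),
    r_thigh = c(0.9, 0.5, 0.7, 0.99, 0.98, 0.97),
    abs_err_flexion_deg = c(1, 2, 3, 4, 5, 6)
  )
  sm <- summarize_validations(trials)
  expect_equal(nrow(sm), 2)
  expect_equal(sm$n_trials, c(3L, 3L))
  i <- which(sm$condition == "normal")
  expect_equal(sm$r_thigh[i], fisher_oracle(c(0.9, 0.5, 0.7)), tolerance = 1e-12)
  expect_equal(sm$abs_err_flexion_deg[i], 2)
})

test_that("trial validation returns tidy metrics for a perturbed trial", {
  trial <- simulate_trial("normal", seed = 9,
                          perturb = perturbation_spec(knee_shift_mm = 20))
  v <- analyze_trial(trial, filter = NULL)
  expect_s3_class(v, "sts_validation")
  g <- glance(v)
  expect_equal(nrow(g), 1)
  expect_true(all(c("r_thigh", "r_trunk_flexion", "r_trunk_extension",
                    "abs_err_flexion_deg", "abs_err_extension_deg") %in% names(g)))
  td <- tidy(v)
  expect_equal(nrow(td), ncol(g))
  expect_true(all(abs(td$value[grepl("^r_", td$metric)]) <= 1, na.rm = TRUE))
  # knee shift harms extension, not flexion
  expect_lt(g$abs_err_flexion_deg, 1)
  expect_gt(g$abs_err_extension_deg, g$abs_err_flexion_deg)
})
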