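test_that("synth_pulse ground truth agrees with the criterion functions", {
  # constant shape: all five closed forms
  sp <- pulse_spec("constant", peak_lin = 100, peak_rot_acc = 2000,
                   peak_rot_vel = 50, duration = 0.02, dt = 1e-4, seed = 1)
  g <- synth_pulse(sp)
  expect_equal(g$truth$HIC, 1500)
  res <- suppressWarnings(compute_all_kinematic(g$record,
                                                criterion_constants()))
  expect_equal(res$HIC$value, g$truth$HIC, tolerance = 1e-9)
  expect_equal(res$GAMBIT$value, g$truth$GAMBIT, tolerance = 1e-9)
  expect_equal(res$BrIC$value, g$truth$BrIC, tolerance = 1e-9)
  expect_equal(suppressWarnings(ric(g$record))$value, g$truth$RIC,
               tolerance = 1e-9)
  expect_equal(res$HIP$value, g$truth$HIP, tolerance = 1e-6)

  # haversine: peak-based truths exact, integral truths numeric
  sh <- synth_pulse(pulse_spec("haversine", peak_lin = 120,
                               peak_rot_acc = 9000, peak_rot_vel = 60,
                               duration = 0.02, dt = 1e-5, seed = 2))
  res_h <- suppressWarnings(compute_all_kinematic(sh$record))
  expect_equal(res_h$GAMBIT$value, sh$truth$GAMBIT, tolerance = 1e-6)
  expect_equal(res_h$BrIC$value, sh$truth$BrIC, tolerance = 1e-6)
  expect_equal(res_h$HIC$value, sh$truth$HIC, tolerance = 1e-4)
  expect_equal(res_h$RIC$value, sh$truth$RIC, tolerance = 1e-4)
  expect_equal(res_h$HIP$value, sh$truth$HIP, tolerance = 1e-4)
  expect_equal(sh$truth$flags[["HIC"]], "numeric")
})

test_that("synth_pulse: zero amplitudes give zero truths; same seed is bit-identical", {
  z <- synth_pulse(pulse_spec("haversine", peak_lin = 0, peak_rot_acc = 0,
                              peak_rot_vel = 0, duration = 0.02,
                              dt = 1e-4, seed = 3))
  expect_true(all(unlist(z$truth[c("HIC", "GAMBIT", "BrIC", "RIC",
                                   "HIP")]) == 0))

  sp <- pulse_spec("triangular", peak_lin = 80, peak_rot_acc = 5000,
                   peak_rot_vel = 30, duration = 0.03, dt = 2e-4,
                   noise_sd = 0.2, seed = 77)
  a <- synth_pulse(sp); b <- synth_pulse(sp)
  expect_identical(a$record$lin_acc, b$record$lin_acc)
  expect_identical(a$record$rot_acc, b$record$rot_acc)
  expect_null(a$truth)  # noisy pulses carry no analytic truth

  expect_error(pulse_spec("constant", duration = 1e-5, dt = 1e-4, seed = 1),
               "duration")
  expect_error(pulse_spec("constant", dir_lin = c(1, 1, 0), seed = 1),
               "unit 3-vector")
})

test_that("synth_element_field hits its target exceedance fractions exactly", {
  # the (1,2,3)-volume hand example: 5/6 above 0.15
  g <- synth_element_field(field_spec(6, "equal",
                                      csdm_thresholds = 0.15,
                                      target_csdm = 5 / 6, seed = 4))
  expect_equal(csdm(g$field, 0.15)$value, 5 / 6)

  for (seed in 1:20) {
    set.seed(seed + 1000)
    tg <- sort(runif(2, 0.05, 0.95), decreasing = TRUE)
    g <- synth_element_field(field_spec(sample(20:200, 1), "lognormal",
                                        csdm_thresholds = c(0.15, 0.25),
                                        target_csdm = tg, seed = seed))
    expect_equal(csdm(g$field, 0.15)$value, tg[1], tolerance = 1e-12)
    expect_equal(csdm(g$field, 0.25)$value, tg[2], tolerance = 1e-12)
    expect_equal(mps(g$field)$value, g$truth$MPS)
    expect_equal(ddm(g$field)$value, g$truth$DDM)
  }

  # boundary targets
  g0 <- synth_element_field(field_spec(10, "equal", csdm_thresholds = 0.15,
                                       target_csdm = 0, seed = 5))
  expect_equal(csdm(g0$field, 0.15)$value, 0)
  g1 <- synth_element_field(field_spec(10, "equal", csdm_thresholds = 0.15,
                                       target_csdm = 1, seed = 6))
  expect_equal(csdm(g1$field, 0.15)$value, 1)

  # unreachable fraction with equal volumes names the nearest reachable one
  expect_error(synth_element_field(field_spec(10, "equal",
                                              csdm_thresholds = 0.15,
                                              target_csdm = 0.8333,
                                              seed = 7)),
               "nearest reachable.*0.8")
})

test_that("synth_cohort recovers its target association and is deterministic", {
  sp <- cohort_spec(5000, target_r = 0.6, seed = 123)
  ch <- synth_cohort(sp)
  r <- pearson_r(ch$criteria$SYNTH, ch$injuries$mais)
  expect_lt(abs(r - 0.6), 0.03)
  expect_true(all(ch$injuries$mais %in% 0:6))

  ch2 <- synth_cohort(sp)
  expect_identical(ch$criteria, ch2$criteria)
  expect_identical(ch$injuries, ch2$injuries)

  # noiseless linear link: r = 1 exactly
  chn <- synth_cohort(cohort_spec(200, target_r = 0.9, noise_sd = 0,
                                  seed = 5))
  expect_equal(pearson_r(chn$criteria$SYNTH, chn$injuries$mais), 1)

  # negative targets flip the sign of the association
  chneg <- synth_cohort(cohort_spec(5000, target_r = -0.5, seed = 9))
  expect_lt(abs(pearson_r(chneg$criteria$SYNTH, chneg$injuries$mais) +
                  0.5), 0.03)

  expect_error(cohort_spec(2, target_r = 0.5, seed = 1), "n_cases")
  expect_error(cohort_spec(10, target_r = 1.2, seed = 1), "target_r")
  expect_error(cohort_spec(10, target_r = 0.5, noise_sd = 0,
                           link = function(m) 1, seed = 1), "degenerate")
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(2024)
  before <- .Random.seed
  invisible(synth_cohort(cohort_spec(50, target_r = 0.5, seed = 1)))
  invisible(synth_element_field(field_spec(10, "lognormal",
                                           target_csdm = c(0.5, 0.2),
                                           seed = 2)))
  expect_identical(.Random.seed, before)
})
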