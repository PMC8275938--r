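test_that("HIC matches closed forms on simple signals", {
  expect_equal(hic(zero_record())$value, 0)

  # constant 100 g over 20 ms, window capped at 15 ms
  t <- seq(0, 0.02, by = 1e-4)
  n <- length(t)
  rec <- kinematics_record(t, cbind(rep(100, n), 0, 0), matrix(0, n, 3),
                           unit_lin = "g")
  res <- hic(rec)
  expect_equal(res$value, 100^2.5 * 0.015, tolerance = 1e-10)
  w <- res$window
  expect_true(w[1] < w[2])
  expect_equal(w[2] - w[1], 0.015, tolerance = 1e-9)

  # pulse shorter than the cap: whole-record window
  t2 <- seq(0, 0.01, by = 1e-4)
  rec2 <- kinematics_record(t2, cbind(rep(50, length(t2)), 0, 0),
                            matrix(0, length(t2), 3), unit_lin = "g")
  expect_equal(hic(rec2)$value, 50^2.5 * 0.01, tolerance = 1e-10)
})

test_that("HIC is unit-consistent and scales as k^2.5", {
  sp <- pulse_spec("haversine", peak_lin = 150, peak_rot_acc = 4000,
                   peak_rot_vel = 40, duration = 0.025, dt = 1e-4, seed = 5)
  rec_g <- synth_pulse(sp)$record
  rec_ms2 <- kinematics_record(rec_g$t, rec_g$lin_acc * rec_g$g_value,
                               rec_g$rot_acc, rec_g$rot_vel,
                               unit_lin = "m_per_s2",
                               g_value = rec_g$g_value)
  expect_equal(hic(rec_ms2)$value, hic(rec_g)$value, tolerance = 1e-12)

  k <- 1.7
  rec_k <- kinematics_record(rec_g$t, rec_g$lin_acc * k, rec_g$rot_acc,
                             rec_g$rot_vel, unit_lin = "g")
  expect_equal(hic(rec_k)$value, k^2.5 * hic(rec_g)$value,
               tolerance = 1e-12)
  expect_gte(gambit(rec_k)$value, gambit(rec_g)$value)
  expect_gte(hip(rec_k)$value, hip(rec_g)$value)
})

test_that("RIC matches the constant closed form and warns on short records", {
  t <- seq(0, 0.05, by = 1e-4)
  n <- length(t)
  rec <- kinematics_record(t, matrix(0, n, 3), cbind(rep(1000, n), 0, 0),
                           unit_lin = "g")
  expect_equal(ric(rec)$value, 1000^2.5 * 0.036, tolerance = 1e-10)
  expect_equal(ric(zero_record(n = 41))$value, 0)  # 40 ms record

  short <- zero_record(n = 11, dt = 1e-3)  # 10 ms < 36 ms window
  expect_warning(ric(short), "full duration")
})

test_that("GAMBIT and BrIC hit their critical-axis values", {
  mk <- function(a, al, w) {
    t <- c(0, 0.005, 0.01)
    kinematics_record(t, cbind(rep(a, 3), 0, 0), cbind(0, 0, rep(al, 3)),
                      cbind(rep(w, 3), 0, 0), unit_lin = "g")
  }
  expect_equal(gambit(mk(350, 0, 0))$value, 1)
  expect_equal(gambit(mk(0, 12000, 0))$value, 1)
  expect_equal(gambit(mk(175, 6000, 0))$value, sqrt(0.5),
               tolerance = 1e-12)
  expect_equal(bric(mk(0, 0, 140))$value, 1)
  expect_equal(bric(mk(0, 12000, 0))$value, 1)
  expect_equal(bric(mk(0, 6000, 70))$value, 1)

  # dimensionless criteria are invariant to a time-axis shift
  rec <- synth_pulse(pulse_spec("triangular", peak_lin = 90,
                                peak_rot_acc = 7000, peak_rot_vel = 50,
                                duration = 0.02, dt = 1e-4,
                                seed = 8))$record
  shifted <- kinematics_record(rec$t + 0.5, rec$lin_acc, rec$rot_acc,
                               rec$rot_vel, unit_lin = "g")
  expect_equal(gambit(shifted)$value, gambit(rec)$value)
  expect_equal(bric(shifted)$value, bric(rec)$value)
})

test_that("HIP matches constant-channel closed forms and takes the signed max", {
  # a_x = 10 m/s^2 on [0, 0.1] s: max P = 4.5 * 10 * (10 * 0.1) = 45 W
  t <- seq(0, 0.1, by = 1e-4)
  n <- length(t)
  rec <- kinematics_record(t, cbind(rep(10, n), 0, 0), matrix(0, n, 3),
                           unit_lin = "m_per_s2")
  expect_equal(hip(rec)$value, 0.045, tolerance = 1e-10)

  # alpha_z = 100 rad/s^2 on [0, 1] s: I_zz * 100 * 100 = 220 W
  t2 <- seq(0, 1, by = 1e-3)
  n2 <- length(t2)
  rec2 <- kinematics_record(t2, matrix(0, n2, 3), cbind(0, 0, rep(100, n2)),
                            unit_lin = "g")
  expect_equal(hip(rec2)$value, 0.22, tolerance = 1e-10)
  expect_equal(hip(zero_record())$value, 0)

  # acceleration then equal-magnitude rebound: power goes negative in the
  # second half; the signed maximum comes from the first half only
  t3 <- seq(0, 0.2, by = 1e-3)
  a <- ifelse(t3 <= 0.1, 10, -10)
  rec3 <- kinematics_record(t3, cbind(a, 0, 0), matrix(0, length(t3), 3),
                            unit_lin = "m_per_s2")
  expect_equal(hip(rec3)$value, 0.045, tolerance = 1e-6)
})

test_that("windowed search equals the exhaustive all-pairs oracle", {
  cc <- criterion_constants()
  for (seed in 1:25) {
    rec <- random_pulse_record(seed, n_max = 400)
    a_g <- resultant(lin_acc_in(rec, "g"))
    al <- resultant(rec$rot_acc)
    expect_equal(hic(rec)$value,
                 brute_window25(rec$t, a_g, cc$hic_window_max),
                 tolerance = 1e-10, label = sprintf("hic seed %d", seed))
    expect_equal(suppressWarnings(ric(rec)$value),
                 brute_window25(rec$t, al, cc$ric_window),
                 tolerance = 1e-10, label = sprintf("ric seed %d", seed))
  }
})

test_that("compute_all_kinematic composes the five criteria in table order", {
  rec <- synth_pulse(pulse_spec("haversine", peak_lin = 80,
                                peak_rot_acc = 6000, peak_rot_vel = 35,
                                duration = 0.04, dt = 1e-4, seed = 3))$record
  all5 <- compute_all_kinematic(rec)
  expect_named(all5, c("HIC", "GAMBIT", "BrIC", "RIC", "HIP"))
  expect_equal(all5$HIC$value, hic(rec)$value)
  expect_equal(all5$GAMBIT$value, gambit(rec)$value)
  expect_equal(all5$BrIC$value, bric(rec)$value)
  expect_equal(all5$RIC$value, ric(rec)$value)
  expect_equal(all5$HIP$value, hip(rec)$value)

  zr <- zero_record(n = 500, dt = 1e-4)  # 50 ms, long enough for RIC
  expect_true(all(vapply(compute_all_kinematic(zr),
                         function(r) r$value, numeric(1)) == 0))
})

test_that("criterion constants validate and override", {
  cc <- criterion_constants(hic_window_max = 0.036)
  expect_equal(cc$hic_window_max, 0.036)
  expect_equal(cc$a_cr, 350)
  expect_error(criterion_constants(bogus = 1), "unknown")
  expect_error(criterion_constants(a_cr = -1), "positive")
})
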