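# Shared helpers: independent brute-force oracles and small generators.

# Exhaustive all-window-pairs search for the windowed power-2.5 maximum,
# written in the natural form (t2 - t1) * mean^2.5 with the window mean
# taken from a cumulative trapezoid. Independent of the package's
# per-left-endpoint scan.
brute_window25 <- function(t, v, wmax) {
  n <- length(t)
  iv <- c(0, cumsum(diff(t) * (v[-n] + v[-1]) / 2))
  dt <- outer(t, t, function(a, b) b - a)     # dt[i, j] = t[j] - t[i]
  di <- outer(iv, iv, function(a, b) b - a)
  ok <- dt > 0 & dt <= wmax * (1 + 1e-12)
  vals <- dt * (di / dt)^2.5
  vals[!ok | !is.finite(vals) | di < 0] <- 0
  max(0, vals, na.rm = TRUE)
}

# A pulse-like record with roughened channels, <= n_max samples.
random_pulse_record <- function(seed, n_max = 500) {
  set.seed(seed)
  dt <- sample(c(1e-4, 2e-4, 5e-4), 1)
  n <- sample(50:n_max, 1)
  sp <- pulse_spec(sample(c("haversine", "triangular", "constant"), 1),
                   peak_lin = runif(1, 20, 250),
                   peak_rot_acc = runif(1, 500, 15000),
                   peak_rot_vel = runif(1, 5, 120),
                   duration = (n - 1) * dt, dt = dt,
                   noise_sd = runif(1, 0.02, 0.3), seed = seed)
  synth_pulse(sp)$record
}

# Minimal two-sample zero record for constructor-level tests.
zero_record <- function(n = 21, dt = 1e-3) {
  t <- seq(0, by = dt, length.out = n)
  kinematics_record(t, matrix(0, n, 3), matrix(0, n, 3), matrix(0, n, 3),
                    unit_lin = "g")
}
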