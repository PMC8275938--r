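# Run code under a local RNG seed without disturbing the caller's stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Unit-normalised pulse shapes on [0, T] and their exact running integrals.
.pulse_shape <- function(shape, t, T) {
  switch(shape,
         constant = rep(1, length(t)),
         haversine = sin(pi * t / T)^2,
         triangular = ifelse(t <= T / 2, 2 * t / T, 2 * (1 - t / T)))
}

.pulse_shape_integral <- function(shape, t, T) {
  switch(shape,
         constant = t,
         haversine = t / 2 - T / (4 * pi) * sin(2 * pi * t / T),
         triangular = ifelse(t <= T / 2, t^2 / T, 2 * t - t^2 / T - T / 2))
}

#' Specify a synthetic crash pulse
#'
#' Describes an idealised head impact pulse: a common dimensionless shape
#' (constant, haversine `sin^2(pi t / T)`, or triangular) scaled per
#' channel group by a peak amplitude and directed along a unit 3-vector.
#' Optional Gaussian channel noise (seeded) roughens the pulse for
#' stress-testing window searches; ground-truth criteria are only
#' available for noiseless pulses.
#'
#' @param shape `"constant"`, `"haversine"` or `"triangular"`.
#' @param peak_lin Peak resultant linear acceleration, g.
#' @param peak_rot_acc Peak resultant rotational acceleration, rad/s^2.
#' @param peak_rot_vel Peak resultant rotational velocity, rad/s.
#' @param duration Pulse duration T, s.
#' @param dt Sample interval, s; must satisfy `duration > dt > 0`.
#' @param dir_lin,dir_rot,dir_vel Unit direction 3-vectors for the linear,
#'   rotational-acceleration and rotational-velocity channel groups.
#' @param noise_sd Standard deviation of additive Gaussian channel noise,
#'   as a fraction of each group's peak (0 = clean pulse).
#' @param seed Integer seed (mandatory; generators have no ambient
#'   randomness).
#' @param g_value m/s^2 per g for the generated record.
#' @return A `pulse_spec` list.
#' @export
pulse_spec <- function(shape = c("haversine", "constant", "triangular"),
                       peak_lin = 100, peak_rot_acc = 5000,
                       peak_rot_vel = 30, duration = 0.02, dt = 1e-4,
                       dir_lin = c(1, 0, 0), dir_rot = c(0, 0, 1),
                       dir_vel = c(0, 0, 1), noise_sd = 0, seed,
                       g_value = 9.81) {
  shape <- match.arg(shape)
  if (missing(seed)) stop("pulse_spec: seed is mandatory", call. = FALSE)
  if (!(duration > dt && dt > 0)) {
    stop("pulse_spec: need duration > dt > 0", call. = FALSE)
  }
  if (min(peak_lin, peak_rot_acc, peak_rot_vel) < 0 || noise_sd < 0) {
    stop("pulse_spec: amplitudes and noise_sd must be non-negative",
         call. = FALSE)
  }
  unitize <- function(d, name) {
    if (length(d) != 3 || abs(sqrt(sum(d^2)) - 1) > 1e-8) {
      stop(sprintf("pulse_spec: `%s` must be a unit 3-vector", name),
           call. = FALSE)
    }
    d
  }
  structure(list(shape = shape, peak_lin = peak_lin,
                 peak_rot_acc = peak_rot_acc, peak_rot_vel = peak_rot_vel,
                 duration = duration, dt = dt,
                 dir_lin = unitize(dir_lin, "dir_lin"),
                 dir_rot = unitize(dir_rot, "dir_rot"),
                 dir_vel = unitize(dir_vel, "dir_vel"),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 g_value = g_value), class = "pulse_spec")
}

# Windowed power-2.5 maximum of A * shape on a dense grid using the exact
# shape integral; reference truth for HIC/RIC of smooth pulses,
# independent of the sampled trapezoid path.
.pulse_window25_truth <- function(shape, A, T, wmax, n_grid = 4001) {
  tg <- seq(0, T, length.out = n_grid)
  Fv <- A * .pulse_shape_integral(shape, tg, T)
  best <- 0
  jmax <- findInterval(tg + wmax + 1e-12 * wmax, tg)
  for (i in seq_len(n_grid - 1)) {
    if (jmax[i] <= i) next
    j <- (i + 1):jmax[i]
    di <- Fv[j] - Fv[i]
    val <- ifelse(di > 0, di^2.5 / (tg[j] - tg[i])^1.5, 0)
    best <- max(best, val)
  }
  best
}

#' Generate a synthetic crash pulse with ground-truth criteria
#'
#' Builds a [kinematics_record()] from a [pulse_spec()] and, for noiseless
#' pulses, attaches ground-truth criterion values: closed forms for the
#' constant shape (all five criteria), exact peak-based GAMBIT/BrIC for
#' every shape, and high-resolution numeric truth (dense grid with exact
#' shape integrals, flagged `"numeric"`) for HIC/RIC/HIP of smooth
#' shapes. Deterministic given the spec (seed included).
#'
#' @param spec A [pulse_spec()].
#' @return List with elements `record` (a `kinematics_record`) and
#'   `truth` (named list of ground-truth values, or `NULL` when
#'   `noise_sd > 0`); `truth$flags` marks each value `"exact"` or
#'   `"numeric"`.
#' @export
#' @examples
#' sp <- pulse_spec("constant", peak_lin = 100, peak_rot_acc = 0,
#'                  peak_rot_vel = 0, duration = 0.02, dt = 1e-4, seed = 1)
#' synth_pulse(sp)$truth$HIC  # 100^2.5 * 0.015 = 1500
synth_pulse <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  f <- .pulse_shape(spec$shape, t, spec$duration)
  lin <- spec$peak_lin * outer(f, spec$dir_lin)
  rot <- spec$peak_rot_acc * outer(f, spec$dir_rot)
  vel <- spec$peak_rot_vel * outer(f, spec$dir_vel)
  if (spec$noise_sd > 0) {
    noise <- .with_seed(spec$seed, list(
      lin = matrix(stats::rnorm(length(lin), 0,
                                spec$noise_sd * max(spec$peak_lin, 1)),
                   nrow(lin)),
      rot = matrix(stats::rnorm(length(rot), 0,
                                spec$noise_sd * max(spec$peak_rot_acc, 1)),
                   nrow(rot)),
      vel = matrix(stats::rnorm(length(vel), 0,
                                spec$noise_sd * max(spec$peak_rot_vel, 1)),
                   nrow(vel))))
    lin <- lin + noise$lin
    rot <- rot + noise$rot
    vel <- vel + noise$vel
  }
  rec <- kinematics_record(t, lin, rot, vel, unit_lin = "g",
                           g_value = spec$g_value,
                           case_id = sprintf("synth_%s_%d", spec$shape,
                                             spec$seed))
  truth <- NULL
  if (spec$noise_sd == 0) {
    cc <- criterion_constants()
    T <- spec$duration
    peak_shape <- max(f)  # 1 when a sample hits the pulse apex
    a_pk <- spec$peak_lin * peak_shape
    al_pk <- spec$peak_rot_acc * peak_shape
    w_pk <- spec$peak_rot_vel * peak_shape
    flags <- c(GAMBIT = "exact", BrIC = "exact")
    if (spec$shape == "constant") {
      hic_v <- spec$peak_lin^2.5 * min(T, cc$hic_window_max)
      ric_v <- spec$peak_rot_acc^2.5 * min(T, cc$ric_window)
      a_ms2 <- spec$peak_lin * spec$g_value
      hip_v <- (cc$head_mass * a_ms2^2 +
                  spec$peak_rot_acc^2 *
                  sum(c(cc$I_xx, cc$I_yy, cc$I_zz) * spec$dir_rot^2)) *
        T / 1000
      flags <- c(flags, HIC = "exact", RIC = "exact", HIP = "exact")
    } else {
      hic_v <- .pulse_window25_truth(spec$shape, spec$peak_lin, T,
                                     cc$hic_window_max)
      ric_v <- .pulse_window25_truth(spec$shape, spec$peak_rot_acc, T,
                                     cc$ric_window)
      tg <- seq(0, T, length.out = 4001)
      fg <- .pulse_shape(spec$shape, tg, T)
      Fg <- .pulse_shape_integral(spec$shape, tg, T)
      a_ms2 <- spec$peak_lin * spec$g_value
      p <- cc$head_mass * (a_ms2 * fg) * (a_ms2 * Fg) +
        sum(c(cc$I_xx, cc$I_yy, cc$I_zz) * spec$dir_rot^2) *
        (spec$peak_rot_acc * fg) * (spec$peak_rot_acc * Fg)
      hip_v <- max(p) / 1000
      flags <- c(flags, HIC = "numeric", RIC = "numeric", HIP = "numeric")
    }
    truth <- list(
      HIC = hic_v,
      GAMBIT = ((a_pk / cc$a_cr)^2 + (al_pk / cc$alpha_cr)^2)^0.5,
      BrIC = w_pk / cc$omega_cr + al_pk / cc$alpha_cr,
      RIC = ric_v,
      HIP = hip_v,
      flags = flags)
  }
  list(record = rec, truth = truth)
}

# ---------------------------------------------------------------------------
# Element fields -------------------------------------------------------------

#' Specify a synthetic brain element field
#'
#' Describes a field of brain elements whose volume-weighted strain
#' exceedance fractions are hit exactly by construction: elements are
#' partitioned into strain bands (below the lowest threshold, between
#' consecutive thresholds, above the highest), each band receives exactly
#' its target share of the total volume, and per-element peak strains are
#' drawn inside the band. With `volume_law = "equal"` all volumes are
#' identical, so targets must be multiples of `1/n_elements`; with
#' `"lognormal"` volumes are lognormal draws renormalised within each
#' band, making any target fraction reachable.
#'
#' @param n_elements Number of elements, >= 1.
#' @param volume_law `"equal"` or `"lognormal"`.
#' @param csdm_thresholds Ascending strain thresholds.
#' @param target_csdm Target exceedance fraction per threshold, in
#'   `[0, 1]`, non-increasing across thresholds.
#' @param pressure_min_mean,pressure_min_sd Normal law (kPa) for the
#'   per-element extreme pressure; defaults centre the bulk of elements
#'   above the -100 kPa tension threshold so DDM values stay small, as
#'   observed in windshield-impact fields.
#' @param timesteps Number of timesteps, >= 2.
#' @param seed Integer seed (mandatory).
#' @return A `field_spec` list.
#' @export
field_spec <- function(n_elements, volume_law = c("equal", "lognormal"),
                       csdm_thresholds = c(0.15, 0.25),
                       target_csdm = c(0.5, 0.25),
                       pressure_min_mean = -40, pressure_min_sd = 35,
                       timesteps = 11, seed) {
  volume_law <- match.arg(volume_law)
  if (missing(seed)) stop("field_spec: seed is mandatory", call. = FALSE)
  if (n_elements < 1) stop("field_spec: n_elements >= 1", call. = FALSE)
  if (timesteps < 2) stop("field_spec: timesteps >= 2", call. = FALSE)
  if (length(target_csdm) != length(csdm_thresholds)) {
    stop("field_spec: one target per threshold required", call. = FALSE)
  }
  if (is.unsorted(csdm_thresholds, strictly = TRUE)) {
    stop("field_spec: thresholds must be strictly ascending", call. = FALSE)
  }
  if (any(target_csdm < 0 | target_csdm > 1)) {
    stop("field_spec: target fractions must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(rev(target_csdm))) {
    stop("field_spec: targets must be non-increasing across ascending thresholds",
         call. = FALSE)
  }
  structure(list(n_elements = as.integer(n_elements),
                 volume_law = volume_law,
                 csdm_thresholds = csdm_thresholds,
                 target_csdm = target_csdm,
                 pressure_min_mean = pressure_min_mean,
                 pressure_min_sd = pressure_min_sd,
                 timesteps = as.integer(timesteps),
                 seed = as.integer(seed)), class = "field_spec")
}

#' Generate a synthetic element field with exact ground truth
#'
#' Constructs an [element_field_history()] whose CSDM at each requested
#' threshold equals its target exactly (see [field_spec()] for the band
#' construction). Strain histories are a haversine time profile scaled to
#' attain each element's drawn peak at a sample; pressure histories dip to
#' a drawn per-element extreme. Ground truth carries the exact CSDM per
#' threshold, MPS and DDM (computed from the drawn extremes by direct
#' volume-weighted counting).
#'
#' @param spec A [field_spec()].
#' @return List with elements `field` (an `element_field_history`) and
#'   `truth` (named list: `CSDM` named by threshold, `MPS`, `DDM`).
#' @export
synth_element_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  n <- spec$n_elements
  th <- spec$csdm_thresholds
  tg <- spec$target_csdm
  K <- length(th)
  # volume share per band: band 0 below th[1]; band k in (th[k], th[k+1]]
  shares <- c(1 - tg[1], -diff(c(tg, 0)))
  if (spec$volume_law == "equal") {
    counts_exact <- shares * n
    counts <- round(counts_exact)
    if (max(abs(counts - counts_exact)) > 1e-9 || sum(counts) != n) {
      reach <- round(tg * n) / n
      stop(sprintf(
        "synth_element_field: target fraction(s) %s unreachable with %d equal volumes; nearest reachable: %s",
        paste(tg, collapse = ", "), n,
        paste(reach, collapse = ", ")), call. = FALSE)
    }
  } else {
    counts <- round(shares * n)
    counts[shares > 0 & counts == 0] <- 1
    # absorb the count mismatch into the largest band
    counts[which.max(counts)] <- counts[which.max(counts)] +
      (n - sum(counts))
    if (any(counts < 0) || sum(counts) != n) {
      stop("synth_element_field: too few elements for the requested bands",
           call. = FALSE)
    }
  }
  .with_seed(spec$seed, {
    band <- rep(seq_along(shares) - 1L, counts)  # 0 .. K
    volume <- numeric(n)
    if (spec$volume_law == "equal") {
      volume[] <- 1 / n
    } else {
      for (b in unique(band)) {
        idx <- which(band == b)
        v <- stats::rlnorm(length(idx), meanlog = 0, sdlog = 0.6)
        volume[idx] <- v / sum(v) * shares[b + 1L]
      }
    }
    peak <- numeric(n)
    lo_floor <- th[1] * 0.25
    for (b in unique(band)) {
      idx <- which(band == b)
      if (b == 0) {
        peak[idx] <- stats::runif(length(idx), lo_floor, th[1] * 0.95)
      } else if (b < K) {
        peak[idx] <- th[b] + (th[b + 1] - th[b]) *
          stats::runif(length(idx), 0.05, 0.95)
      } else {
        peak[idx] <- th[K] * (1 + stats::runif(length(idx), 0.1, 1.5))
      }
    }
    pmin_e <- stats::rnorm(n, spec$pressure_min_mean, spec$pressure_min_sd)
    k <- spec$timesteps
    tt <- seq(0, 0.02, length.out = k)
    prof <- sin(pi * seq(0, 1, length.out = k))^2
    prof <- prof / max(prof)  # peak attained exactly at a sample
    field <- element_field_history(
      element_id = seq_len(n), volume = volume, t = tt,
      strain = outer(peak, prof),
      pressure = outer(pmin_e, prof))
    truth <- list(
      CSDM = stats::setNames(tg, sprintf("CSDM_%g", th)),
      MPS = max(peak),
      DDM = sum(volume[pmin_e < -100]) / sum(volume))
    list(field = field, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Criterion-injury cohorts ---------------------------------------------------

# MAIS cut-points on the standard-normal latent severity scale. The
# cumulative class probabilities mirror the empirical MAIS distribution of
# the packaged 31-case cohort (3, 7, 5, 2, 5, 5, 4 cases at MAIS 0-6).
.mais_cutpoints <- stats::qnorm(cumsum(c(3, 7, 5, 2, 5, 5)) / 31)

#' Specify a synthetic criterion-injury cohort
#'
#' Describes a cohort of cases with a latent standard-normal severity,
#' a MAIS score obtained by discretising the severity at fixed cut-points
#' (mirroring the packaged cohort's MAIS distribution), and a criterion
#' value built as `link(MAIS) + noise`. The noise standard deviation is
#' derived from `target_r` so that the population Pearson correlation
#' between the criterion and MAIS equals `target_r` exactly when `link`
#' is linear; a supplied `noise_sd` overrides the derivation.
#'
#' @param n_cases Number of cases, >= 3.
#' @param target_r Desired criterion-MAIS Pearson correlation, in
#'   (-1, 1), non-zero.
#' @param link Monotone link from MAIS to the expected criterion value;
#'   default identity. Non-linear links make `target_r` approximate.
#' @param noise_sd Optional override of the derived noise standard
#'   deviation.
#' @param criterion_name Column name for the generated criterion.
#' @param seed Integer seed (mandatory).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases, target_r = 0.6, link = identity,
                        noise_sd = NULL, criterion_name = "SYNTH", seed) {
  if (missing(seed)) stop("cohort_spec: seed is mandatory", call. = FALSE)
  if (n_cases < 3) stop("cohort_spec: n_cases >= 3", call. = FALSE)
  if (abs(target_r) >= 1 || target_r == 0) {
    stop("cohort_spec: target_r must lie in (-1, 1) and be non-zero",
         call. = FALSE)
  }
  if (!is.null(noise_sd) && noise_sd == 0) {
    lk <- vapply(0:6, link, numeric(1))
    if (max(lk) - min(lk) == 0) {
      stop("cohort_spec: noise_sd 0 with a constant link is degenerate",
           call. = FALSE)
    }
  }
  structure(list(n_cases = as.integer(n_cases), target_r = target_r,
                 link = link, noise_sd = noise_sd,
                 criterion_name = criterion_name, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic criterion-injury cohort
#'
#' @param spec A [cohort_spec()].
#' @return List with `criteria` (data.frame: `case_id`, criterion column),
#'   `injuries` (data.frame: `case_id`, `mais`) and `truth` (the target
#'   correlation, the latent severities, the MAIS cut-points and the noise
#'   standard deviation used).
#' @export
#' @examples
#' ch <- synth_cohort(cohort_spec(500, target_r = 0.6, seed = 7))
#' pearson_r(ch$criteria$SYNTH, ch$injuries$mais)
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cuts <- .mais_cutpoints
  # population moments of the discretised MAIS under the normal latent
  p <- diff(c(0, stats::pnorm(cuts), 1))
  mu <- sum((0:6) * p)
  sd_m <- sqrt(sum((0:6)^2 * p) - mu^2)
  rho <- abs(spec$target_r)
  noise_sd <- if (is.null(spec$noise_sd)) {
    sd_m * sqrt(1 / rho^2 - 1)
  } else {
    spec$noise_sd
  }
  .with_seed(spec$seed, {
    z <- stats::rnorm(spec$n_cases)
    mais <- findInterval(z, cuts)
    x <- sign(spec$target_r) * vapply(mais, spec$link, numeric(1)) +
      stats::rnorm(spec$n_cases, 0, noise_sd)
    criteria <- data.frame(case_id = seq_len(spec$n_cases), x)
    names(criteria)[2] <- spec$criterion_name
    injuries <- data.frame(case_id = seq_len(spec$n_cases), mais = mais)
    list(criteria = criteria, injuries = injuries,
         truth = list(target_r = spec$target_r, latent = z,
                      cutpoints = cuts, noise_sd = noise_sd,
                      mais_sd_population = sd_m))
  })
}
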