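# ---------------------------------------------------------------------------
# Criterion constants --------------------------------------------------------

#' Constants used by the kinematic head injury criteria
#'
#' Returns the set of critical values, head inertial properties and window
#' lengths the five kinematic criteria depend on. Defaults are the values
#' conventionally used with these criteria for an adult head:
#'
#' * `a_cr` = 350 g, `alpha_cr` = 12000 rad/s^2 — GAMBIT critical linear and
#'   rotational accelerations (the latter also normalises BrIC);
#' * `omega_cr` = 140 rad/s — BrIC critical rotational velocity;
#' * `gambit_n`, `gambit_m`, `gambit_s` = 2 — GAMBIT exponents;
#' * `head_mass` = 4.5 kg, `I_xx` = 0.016, `I_yy` = 0.024,
#'   `I_zz` = 0.022 kg m^2 — HIP inertial properties of the head;
#' * `hic_window_max` = 0.015 s — HIC15 window cap (set 0.036 for HIC36);
#' * `ric_window` = 0.036 s — RIC window cap.
#'
#' @param ... Named overrides for any of the defaults.
#' @return A list of class `criterion_constants`.
#' @export
#' @examples
#' criterion_constants(hic_window_max = 0.036)  # HIC36 variant
criterion_constants <- function(...) {
  cc <- list(a_cr = 350, alpha_cr = 12000, omega_cr = 140,
             gambit_n = 2, gambit_m = 2, gambit_s = 2,
             head_mass = 4.5, I_xx = 0.016, I_yy = 0.024, I_zz = 0.022,
             hic_window_max = 0.015, ric_window = 0.036)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cc))
  if (length(unknown)) {
    stop(sprintf("criterion_constants: unknown constant(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cc[names(dots)] <- dots
  bad <- names(cc)[!vapply(cc, function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop(sprintf("criterion_constants: constant(s) must be positive scalars: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(cc, class = "criterion_constants")
}

.criterion_result <- function(name, value, units, window = NULL,
                              params = list()) {
  if (!is.finite(value)) {
    stop(sprintf("%s: computed value is not finite", name), call. = FALSE)
  }
  structure(list(name = name, value = value, units = units,
                 window = window, params = params),
            class = "criterion_result")
}

#' @export
print.criterion_result <- function(x, ...) {
  win <- if (!is.null(x$window)) {
    sprintf(" (window %.4g-%.4g ms)", 1000 * x$window[1], 1000 * x$window[2])
  } else ""
  cat(sprintf("%s = %.6g %s%s\n", x$name, x$value, x$units, win))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Windowed power-2.5 maximisation (shared by HIC and RIC) --------------------

# Maximise (t2 - t1) * (mean of v over [t1, t2])^2.5 over sample-aligned
# windows with 0 < t2 - t1 <= wmax, via the cumulative trapezoid integral:
# value = (I[j] - I[i])^2.5 / (t[j] - t[i])^1.5. One pass per left endpoint,
# vectorised over admissible right endpoints.
.window_max_25 <- function(t, v, wmax) {
  n <- length(t)
  iv <- c(0, cumsum(diff(t) * (v[-n] + v[-1]) / 2))
  best <- 0
  best_win <- c(t[1], t[2])
  jmax <- findInterval(t + wmax + 1e-12 * wmax, t)
  for (i in seq_len(n - 1)) {
    if (jmax[i] <= i) next  # sampling coarser than the window cap
    j <- (i + 1):jmax[i]
    di <- iv[j] - iv[i]
    # negative window means -> NaN under ^2.5; treat as non-candidates
    val <- ifelse(di > 0, di^2.5 / (t[j] - t[i])^1.5, 0)
    k <- which.max(val)
    if (val[k] > best) {
      best <- val[k]
      best_win <- c(t[i], t[j[k]])
    }
  }
  list(value = best, window = best_win)
}

# ---------------------------------------------------------------------------
# HIC -------------------------------------------------------------------------

#' Head injury criterion (HIC15)
#'
#' HIC = max over windows `[t1, t2]` of
#' `(t2 - t1) * ((1 / (t2 - t1)) * integral of a(t) dt)^2.5`, where `a(t)`
#' is the resultant linear acceleration of the head centroid in g. Window
#' endpoints are restricted to sample times; the window length is capped at
#' `constants$hic_window_max` (15 ms by default, the HIC15 definition; set
#' the cap to 36 ms for HIC36).
#'
#' @param rec A [kinematics_record()].
#' @param constants A [criterion_constants()] list.
#' @return A `criterion_result` with the HIC value (dimensionless) and the
#'   maximising window in seconds.
#' @export
#' @examples
#' t <- seq(0, 0.02, by = 1e-4)
#' rec <- kinematics_record(t, cbind(rep(100, length(t)), 0, 0),
#'                          matrix(0, length(t), 3), unit_lin = "g")
#' hic(rec)$value  # 100^2.5 * 0.015 = 1500
hic <- function(rec, constants = criterion_constants()) {
  a <- resultant(lin_acc_in(rec, "g"))
  wm <- .window_max_25(rec$t, a, constants$hic_window_max)
  .criterion_result("HIC", wm$value, "-", wm$window,
                    list(hic_window_max = constants$hic_window_max,
                         g_value = rec$g_value))
}

#' Rotational injury criterion (RIC)
#'
#' The rotational analogue of HIC: the same windowed power-2.5
#' maximisation applied to the resultant rotational acceleration (rad/s^2)
#' with the window length capped at `constants$ric_window` (36 ms). For
#' impact pulses of severe cases the value is of order 1e7-1e8.
#'
#' If the record is shorter than the window cap the maximisation runs over
#' the full duration and a warning is issued.
#'
#' @inheritParams hic
#' @return A `criterion_result` (dimensionless value, window in s).
#' @export
ric <- function(rec, constants = criterion_constants()) {
  al <- resultant(rec$rot_acc)
  dur <- diff(range(rec$t))
  if (dur < constants$ric_window) {
    warning(sprintf(
      "ric: record duration %.4g s is shorter than the %.4g s window; evaluating over the full duration",
      dur, constants$ric_window), call. = FALSE)
  }
  wm <- .window_max_25(rec$t, al, constants$ric_window)
  .criterion_result("RIC", wm$value, "-", wm$window,
                    list(ric_window = constants$ric_window))
}

#' Generalized Acceleration Model for Brain Injury Threshold (GAMBIT)
#'
#' `GAMBIT = ((a_max / a_cr)^n + (alpha_max / alpha_cr)^m)^(1/s)` with peak
#' resultant linear acceleration `a_max` (g), peak resultant rotational
#' acceleration `alpha_max` (rad/s^2), critical values `a_cr` = 350 g and
#' `alpha_cr` = 12000 rad/s^2, and exponents n = m = s = 2 by default.
#'
#' @inheritParams hic
#' @return A `criterion_result` (dimensionless).
#' @export
gambit <- function(rec, constants = criterion_constants()) {
  a_max <- max(resultant(lin_acc_in(rec, "g")))
  al_max <- max(resultant(rec$rot_acc))
  val <- ((a_max / constants$a_cr)^constants$gambit_n +
            (al_max / constants$alpha_cr)^constants$gambit_m)^
    (1 / constants$gambit_s)
  .criterion_result("GAMBIT", val, "-", NULL,
                    list(a_cr = constants$a_cr, alpha_cr = constants$alpha_cr,
                         n = constants$gambit_n, m = constants$gambit_m,
                         s = constants$gambit_s))
}

#' Head impact power (HIP)
#'
#' The peak of the instantaneous mechanical power delivered to the head:
#' `P(t) = m * sum_i a_i(t) * int_0^t a_i dtau
#'        + sum_i I_ii * alpha_i(t) * int_0^t alpha_i dtau`
#' over the axes i in x, y, z, with linear acceleration in m/s^2 and
#' rotational acceleration in rad/s^2. The signed maximum is taken (power
#' can be negative during rebound; no absolute value). Reported in kW.
#'
#' @inheritParams hic
#' @return A `criterion_result` in kW, with the time of peak power stored
#'   as a degenerate window.
#' @export
hip <- function(rec, constants = criterion_constants()) {
  a <- lin_acc_in(rec, "m_per_s2")
  al <- rec$rot_acc
  I <- c(constants$I_xx, constants$I_yy, constants$I_zz)
  p <- numeric(length(rec$t))
  for (i in 1:3) {
    p <- p + constants$head_mass * a[, i] * running_integral(a[, i], rec$t) +
      I[i] * al[, i] * running_integral(al[, i], rec$t)
  }
  k <- which.max(p)
  .criterion_result("HIP", p[k] / 1000, "kW", NULL,
                    list(head_mass = constants$head_mass,
                         I_xx = I[1], I_yy = I[2], I_zz = I[3],
                         t_peak = rec$t[k]))
}

#' Brain injury criterion (BrIC)
#'
#' `BrIC = omega_max / omega_cr + alpha_max / alpha_cr` with peak resultant
#' rotational velocity (rad/s) and peak resultant rotational acceleration
#' (rad/s^2), critical values 140 rad/s and 12000 rad/s^2.
#'
#' @inheritParams hic
#' @return A `criterion_result` (dimensionless).
#' @export
bric <- function(rec, constants = criterion_constants()) {
  if (is.null(rec$rot_vel)) {
    stop("bric: record has no rotational-velocity channels", call. = FALSE)
  }
  w_max <- max(resultant(rec$rot_vel))
  al_max <- max(resultant(rec$rot_acc))
  val <- w_max / constants$omega_cr + al_max / constants$alpha_cr
  .criterion_result("BrIC", val, "-", NULL,
                    list(omega_cr = constants$omega_cr,
                         alpha_cr = constants$alpha_cr))
}

#' Compute all five kinematic criteria for a record
#'
#' Convenience wrapper returning HIC, GAMBIT, BrIC, RIC and HIP (in that
#' order) for one record, identical to calling the five criterion
#' functions separately.
#'
#' @inheritParams hic
#' @return Named list of `criterion_result` objects in the order
#'   HIC, GAMBIT, BrIC, RIC, HIP.
#' @export
compute_all_kinematic <- function(rec, constants = criterion_constants()) {
  fns <- list(HIC = hic, GAMBIT = gambit, BrIC = bric, RIC = ric, HIP = hip)
  out <- vector("list", length(fns))
  names(out) <- names(fns)
  for (nm in names(fns)) {
    out[[nm]] <- tryCatch(fns[[nm]](rec, constants), error = function(e) {
      stop(sprintf("%s: %s", nm, conditionMessage(e)), call. = FALSE)
    })
  }
  out
}

#' Tabulate kinematic criteria across records
#'
#' @param recs List of [kinematics_record()] objects.
#' @param constants A [criterion_constants()] list.
#' @return A data.frame with one row per record and columns `case_id`,
#'   `HIC`, `GAMBIT`, `BrIC`, `RIC`, `HIP`.
#' @export
criteria_table <- function(recs, constants = criterion_constants()) {
  rows <- lapply(recs, function(r) {
    res <- compute_all_kinematic(r, constants)
    data.frame(case_id = r$case_id,
               HIC = res$HIC$value, GAMBIT = res$GAMBIT$value,
               BrIC = res$BrIC$value, RIC = res$RIC$value,
               HIP = res$HIP$value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
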