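# ---------------------------------------------------------------------------
# Scalar time series -------------------------------------------------------

#' Create a scalar time series
#'
#' A minimal container pairing a strictly increasing time vector (seconds)
#' with a value vector of the same length. Used for channel resultants and
#' running integrals feeding the injury-criterion computations.
#'
#' @param t Numeric time vector in seconds, strictly increasing.
#' @param v Numeric value vector, same length as `t`.
#' @param unit Character unit label carried as metadata (not used in
#'   computation).
#' @return An object of class `scalar_series` with elements `t`, `v`, `unit`.
#' @export
#' @examples
#' s <- scalar_series(seq(0, 0.01, by = 0.001), sin(1:11))
scalar_series <- function(t, v, unit = "") {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v)) {
    stop("scalar_series: `t` and `v` must have equal length", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("scalar_series: time vector must be strictly increasing",
         call. = FALSE)
  }
  structure(list(t = t, v = v, unit = unit), class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %d samples, t in [%g, %g] s%s\n",
              length(x$t), min(x$t), max(x$t),
              if (nzchar(x$unit)) paste0(", unit: ", x$unit) else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Kinematics record ---------------------------------------------------------

#' Create a head kinematics record
#'
#' Bundles the time-aligned head centre-of-gravity channels needed by the
#' kinematic injury criteria: 3-axis linear acceleration, 3-axis rotational
#' acceleration and (optionally) 3-axis rotational velocity.
#'
#' Linear acceleration may be stored either in g or in m/s^2; the declared
#' unit plus the g conversion factor travel with the record so every
#' criterion can convert lazily to the unit its formula requires.
#'
#' @param t Time vector in seconds, strictly increasing, length >= 2.
#' @param lin_acc Numeric matrix (n x 3) of linear acceleration, columns
#'   x, y, z, in the unit declared by `unit_lin`.
#' @param rot_acc Numeric matrix (n x 3) of rotational acceleration in
#'   rad/s^2.
#' @param rot_vel Optional numeric matrix (n x 3) of rotational velocity in
#'   rad/s; `NULL` when the source file carried no velocity channels (BrIC
#'   then cannot be computed from the record).
#' @param unit_lin Either `"g"` or `"m_per_s2"`.
#' @param g_value Conversion factor, m/s^2 per g. Defaults to 9.81;
#'   set 9.8 to follow sources that use that rounding.
#' @param case_id Character label for the record.
#' @return An object of class `kinematics_record`.
#' @export
#' @examples
#' t <- seq(0, 0.02, by = 1e-4)
#' a <- cbind(100 * sin(pi * t / 0.02)^2, 0, 0)
#' rec <- kinematics_record(t, a, matrix(0, length(t), 3),
#'                          matrix(0, length(t), 3), unit_lin = "g")
kinematics_record <- function(t, lin_acc, rot_acc, rot_vel = NULL,
                              unit_lin = c("g", "m_per_s2"),
                              g_value = 9.81, case_id = "") {
  unit_lin <- match.arg(unit_lin)
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2) {
    stop("kinematics_record: at least 2 samples required", call. = FALSE)
  }
  if (any(diff(t) <= 0)) {
    stop("kinematics_record: time vector must be strictly increasing",
         call. = FALSE)
  }
  if (!is.numeric(g_value) || length(g_value) != 1 || g_value <= 0) {
    stop("kinematics_record: g_value must be a positive scalar",
         call. = FALSE)
  }
  as_chan <- function(m, name) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (nrow(m) != n || ncol(m) != 3) {
      stop(sprintf("kinematics_record: `%s` must be an n x 3 matrix", name),
           call. = FALSE)
    }
    if (anyNA(m)) {
      stop(sprintf("kinematics_record: NaN/NA in `%s` channels", name),
           call. = FALSE)
    }
    colnames(m) <- c("x", "y", "z")
    m
  }
  lin_acc <- as_chan(lin_acc, "lin_acc")
  rot_acc <- as_chan(rot_acc, "rot_acc")
  if (!is.null(rot_vel)) rot_vel <- as_chan(rot_vel, "rot_vel")
  structure(list(case_id = as.character(case_id), t = t,
                 lin_acc = lin_acc, rot_acc = rot_acc, rot_vel = rot_vel,
                 unit_lin = unit_lin, g_value = g_value),
            class = "kinematics_record")
}

#' @export
print.kinematics_record <- function(x, ...) {
  cat(sprintf("<kinematics_record> %s%d samples over %.4g ms, lin unit %s%s\n",
              if (nzchar(x$case_id)) paste0("case ", x$case_id, ", ") else "",
              length(x$t), 1000 * diff(range(x$t)), x$unit_lin,
              if (is.null(x$rot_vel)) ", no rotational velocity" else ""))
  invisible(x)
}

#' Linear acceleration of a record in a requested unit
#'
#' @param rec A [kinematics_record()].
#' @param unit Target unit, `"g"` or `"m_per_s2"`.
#' @return n x 3 matrix in the requested unit.
#' @export
lin_acc_in <- function(rec, unit = c("g", "m_per_s2")) {
  unit <- match.arg(unit)
  a <- rec$lin_acc
  if (unit == rec$unit_lin) return(a)
  if (unit == "g") a / rec$g_value else a * rec$g_value
}

# ---------------------------------------------------------------------------
# Resultant and integration -------------------------------------------------

#' Elementwise Euclidean resultant of three channel series
#'
#' Computes sqrt(x^2 + y^2 + z^2) per sample, e.g. the resultant linear
#' acceleration of the head centroid from its axis components.
#'
#' @param x,y,z Numeric vectors of equal length, or a single n x 3 matrix
#'   passed as `x` with `y`, `z` missing.
#' @param t Optional time vector; when supplied the result is a
#'   [scalar_series()], otherwise a bare numeric vector.
#' @param unit Unit label forwarded to the series.
#' @return Numeric vector or `scalar_series` of per-sample norms.
#' @export
#' @examples
#' resultant(3, 4, 0)  # 5
resultant <- function(x, y = NULL, z = NULL, t = NULL, unit = "") {
  if (is.matrix(x) && is.null(y) && is.null(z)) {
    y <- x[, 2]; z <- x[, 3]; x <- x[, 1]
  }
  if (length(y) != length(x) || length(z) != length(x)) {
    stop("resultant: component series must have equal length", call. = FALSE)
  }
  r <- sqrt(x^2 + y^2 + z^2)
  if (is.null(t)) r else scalar_series(t, r, unit)
}

#' Running (cumulative) trapezoidal integral of a series
#'
#' First value is 0; the time vector is preserved. The trapezoidal rule is
#' exact for piecewise-linear integrands and handles non-uniform sampling.
#'
#' @param s A [scalar_series()], or a numeric value vector with `t` given.
#' @param t Time vector when `s` is a bare vector.
#' @return A `scalar_series` of the running integral (or a numeric vector
#'   when the input was a bare vector).
#' @export
running_integral <- function(s, t = NULL) {
  bare <- !inherits(s, "scalar_series")
  if (bare) {
    v <- as.numeric(s)
  } else {
    v <- s$v; t <- s$t
  }
  if (length(t) != length(v)) {
    stop("running_integral: time and value lengths differ", call. = FALSE)
  }
  if (length(v) < 2) {
    stop("running_integral: at least 2 samples required", call. = FALSE)
  }
  iv <- c(0, cumsum(diff(t) * (v[-length(v)] + v[-1]) / 2))
  if (bare) iv else scalar_series(t, iv, paste0(s$unit, "*s"))
}

# ---------------------------------------------------------------------------
# CFC channel filtering ------------------------------------------------------

# -3 dB cutoff frequencies (Hz) of the channel frequency classes used for
# crash-test signals; the filter is a 2-pole Butterworth run forward and
# backward (4-pole phaseless response).
.cfc_cutoff <- c(CFC60 = 100, CFC180 = 300, CFC600 = 1000, CFC1000 = 1650)

#' Phaseless channel-frequency-class low-pass filter
#'
#' Applies the crash-signal channel-class convention: a 2-pole Butterworth
#' low-pass run forward and backward (zero phase, 4-pole magnitude
#' response) at the class cutoff. With `cfc_class = "none"` the input is
#' returned untouched; no filtering is ever applied implicitly by the
#' criterion functions.
#'
#' @param s A [scalar_series()] with uniform sampling.
#' @param cfc_class One of `"CFC60"`, `"CFC180"`, `"CFC600"`, `"CFC1000"`,
#'   `"none"`.
#' @return Filtered `scalar_series`.
#' @export
cfc_filter <- function(s, cfc_class = c("none", "CFC60", "CFC180",
                                        "CFC600", "CFC1000")) {
  cfc_class <- match.arg(cfc_class)
  if (!inherits(s, "scalar_series")) {
    stop("cfc_filter: input must be a scalar_series", call. = FALSE)
  }
  if (cfc_class == "none") return(s)
  dt <- diff(s$t)
  if (max(dt) - min(dt) > 1e-9 * mean(dt)) {
    stop("cfc_filter: uniform sampling required for filtering",
         call. = FALSE)
  }
  fs <- 1 / mean(dt)
  fc <- .cfc_cutoff[[cfc_class]]
  if (fc >= fs / 2) {
    stop(sprintf(
      "cfc_filter: class cutoff %g Hz is at/above the Nyquist frequency %g Hz",
      fc, fs / 2), call. = FALSE)
  }
  bf <- signal::butter(2, fc / (fs / 2), type = "low")
  # odd-reflection padding suppresses forward-backward edge transients
  # (and makes the DC gain exactly 1 on constant signals)
  x <- s$v
  n <- length(x)
  p <- min(n - 1, max(12, ceiling(3 * fs / fc)))
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  v <- signal::filtfilt(bf, c(pre, x, post))[(p + 1):(p + n)]
  scalar_series(s$t, v, s$unit)
}

# ---------------------------------------------------------------------------
# Readers / writers ---------------------------------------------------------

.kin_cols <- c("t", "ax", "ay", "az", "alx", "aly", "alz")
.kin_vel_cols <- c("wx", "wy", "wz")

#' Read a head kinematics time-history file
#'
#' Expects delimited text (comma by default, tab accepted) with a header
#' naming columns `t, ax, ay, az, alx, aly, alz` and optionally
#' `wx, wy, wz` (rotational velocity). Lines starting with `#` are
#' comments. Units are supplied by the caller, not inferred from the file.
#'
#' @param path Path to the delimited text file.
#' @param unit_lin Unit of the linear-acceleration columns.
#' @param g_value m/s^2 per g, used for later conversions.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @param case_id Label stored in the record; defaults to the file name.
#' @return A validated [kinematics_record()].
#' @export
read_kinematics <- function(path, unit_lin = c("g", "m_per_s2"),
                            g_value = 9.81, delim = ",",
                            case_id = basename(path)) {
  unit_lin <- match.arg(unit_lin)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          comment.char = "#", check.names = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(.kin_cols, names(df))
  if (length(missing)) {
    stop(sprintf("read_kinematics: missing mandatory column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  has_vel <- all(.kin_vel_cols %in% names(df))
  kinematics_record(
    t = df$t,
    lin_acc = cbind(df$ax, df$ay, df$az),
    rot_acc = cbind(df$alx, df$aly, df$alz),
    rot_vel = if (has_vel) cbind(df$wx, df$wy, df$wz) else NULL,
    unit_lin = unit_lin, g_value = g_value, case_id = case_id)
}

#' Write a kinematics record to delimited text
#'
#' Inverse of [read_kinematics()]; full double precision is retained so a
#' write/read round trip reproduces the record to machine precision.
#'
#' @param rec A [kinematics_record()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(rec, path, delim = ",") {
  df <- data.frame(t = rec$t,
                   ax = rec$lin_acc[, 1], ay = rec$lin_acc[, 2],
                   az = rec$lin_acc[, 3],
                   alx = rec$rot_acc[, 1], aly = rec$rot_acc[, 2],
                   alz = rec$rot_acc[, 3])
  if (!is.null(rec$rot_vel)) {
    df$wx <- rec$rot_vel[, 1]
    df$wy <- rec$rot_vel[, 2]
    df$wz <- rec$rot_vel[, 3]
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = delim), con)
  body <- do.call(paste, c(lapply(df, function(x) {
    formatC(x, format = "g", digits = 17)
  }), sep = delim))
  writeLines(body, con)
  invisible(path)
}
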