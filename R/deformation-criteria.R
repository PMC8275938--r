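# ---------------------------------------------------------------------------
# Element field history ------------------------------------------------------

#' Create a brain element field history
#'
#' Holds the per-element volume together with first-principal-strain and
#' pressure time series for every brain element, as exported by an
#' upstream finite-element solver. Strains are dimensionless
#' (Green-Lagrange first principal strain as provided); pressure is in kPa
#' with positive values meaning compression, so tension shows up as
#' negative pressure.
#'
#' @param element_id Integer vector of unique element labels (length m).
#' @param volume Strictly positive per-element volumes (length m), any
#'   consistent volume unit; treated as constant over time.
#' @param t Time vector in seconds, strictly increasing (length k).
#' @param strain m x k matrix of first principal strain.
#' @param pressure m x k matrix of pressure in kPa (positive =
#'   compression). May be `NULL` when only strain metrics are needed.
#' @return An object of class `element_field_history`.
#' @export
element_field_history <- function(element_id, volume, t, strain,
                                  pressure = NULL) {
  element_id <- as.integer(element_id)
  m <- length(element_id)
  if (m < 1) {
    stop("element_field_history: at least one element required",
         call. = FALSE)
  }
  if (anyDuplicated(element_id)) {
    stop("element_field_history: element_id must be unique", call. = FALSE)
  }
  volume <- as.numeric(volume)
  if (length(volume) != m || any(!is.finite(volume)) || any(volume <= 0)) {
    stop("element_field_history: volumes must be strictly positive, one per element",
         call. = FALSE)
  }
  t <- as.numeric(t)
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("element_field_history: time vector must be strictly increasing",
         call. = FALSE)
  }
  chk <- function(x, name) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) != m || ncol(x) != length(t)) {
      stop(sprintf(
        "element_field_history: `%s` must be elements x timesteps (%d x %d)",
        name, m, length(t)), call. = FALSE)
    }
    if (anyNA(x)) {
      stop(sprintf("element_field_history: NaN/NA in `%s`", name),
           call. = FALSE)
    }
    x
  }
  strain <- chk(strain, "strain")
  if (!is.null(pressure)) pressure <- chk(pressure, "pressure")
  structure(list(element_id = element_id, volume = volume, t = t,
                 strain = strain, pressure = pressure),
            class = "element_field_history")
}

#' @export
print.element_field_history <- function(x, ...) {
  cat(sprintf("<element_field_history> %d elements x %d timesteps, total volume %.6g%s\n",
              length(x$element_id), length(x$t), sum(x$volume),
              if (is.null(x$pressure)) ", strain only" else ""))
  invisible(x)
}

#' Read an element field history from long-format delimited text
#'
#' Expects columns `element_id, volume, t, strain, pressure` with every
#' element present at every timestep (a complete grid); lines starting
#' with `#` are comments (used for unit documentation). The `pressure`
#' column may be omitted.
#'
#' @param path Path to the delimited text file.
#' @param delim Field delimiter; `","` (default) or `"\t"`.
#' @return A validated [element_field_history()].
#' @export
read_element_fields <- function(path, delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element_id", "volume", "t", "strain")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("read_element_fields: missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  ids <- sort(unique(df$element_id))
  ts <- sort(unique(df$t))
  if (nrow(df) != length(ids) * length(ts)) {
    stop("read_element_fields: ragged grid - every element must appear at every timestep",
         call. = FALSE)
  }
  key <- paste(df$element_id, df$t)
  full <- paste(rep(ids, each = length(ts)), rep(ts, length(ids)))
  if (anyDuplicated(key) || !all(full %in% key)) {
    stop("read_element_fields: ragged grid - every element must appear at every timestep",
         call. = FALSE)
  }
  df <- df[order(match(df$element_id, ids), df$t), ]
  vol <- df$volume[!duplicated(df$element_id)]
  per_el_vol <- tapply(df$volume, df$element_id, function(v) length(unique(v)))
  if (any(per_el_vol != 1)) {
    stop("read_element_fields: element volume must be constant over time",
         call. = FALSE)
  }
  k <- length(ts)
  element_field_history(
    element_id = ids, volume = vol, t = ts,
    strain = matrix(df$strain, ncol = k, byrow = TRUE),
    pressure = if ("pressure" %in% names(df)) {
      matrix(df$pressure, ncol = k, byrow = TRUE)
    } else NULL)
}

#' Write an element field history to long-format delimited text
#'
#' @param field An [element_field_history()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_element_fields <- function(field, path, delim = ",") {
  m <- length(field$element_id)
  k <- length(field$t)
  df <- data.frame(element_id = rep(field$element_id, each = k),
                   volume = rep(field$volume, each = k),
                   t = rep(field$t, m),
                   strain = as.vector(t(field$strain)))
  if (!is.null(field$pressure)) df$pressure <- as.vector(t(field$pressure))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# units: volume consistent, t s, strain -, pressure kPa (positive = compression)",
               paste(names(df), collapse = delim)), con)
  writeLines(do.call(paste, c(lapply(df, function(x) {
    if (is.numeric(x)) formatC(x, format = "g", digits = 17) else x
  }), sep = delim)), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Deformation criteria -------------------------------------------------------

#' Maximum principal strain (MPS)
#'
#' The peak first principal strain over all elements and all timesteps
#' (the global element-wise maximum, not a volume percentile). Values can
#' exceed 1 for severe impacts.
#'
#' @param field An [element_field_history()].
#' @return A `criterion_result` (dimensionless).
#' @export
mps <- function(field) {
  .criterion_result("MPS", max(field$strain), "-")
}

#' Cumulative strain damage measure (CSDM)
#'
#' The fraction of brain volume whose first principal strain exceeds a
#' threshold at any timestep ("once exceeded, always counted"):
#' sum of volumes of elements with peak strain above the threshold,
#' divided by the total volume. Conventional thresholds are 0.15 and 0.25.
#'
#' @param field An [element_field_history()].
#' @param threshold Strain threshold, > 0. Default 0.15.
#' @param strict If `TRUE` (default) exceedance is strict (`>`); set
#'   `FALSE` for inclusive (`>=`) comparison.
#' @return A `criterion_result` with value in `[0, 1]`.
#' @export
#' @examples
#' f <- element_field_history(1:3, c(1, 2, 3), c(0, 1e-3),
#'                            strain = cbind(0, c(0.10, 0.20, 0.30)))
#' csdm(f, 0.15)$value  # (2 + 3) / 6
csdm <- function(field, threshold = 0.15, strict = TRUE) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("csdm: threshold must be a positive scalar", call. = FALSE)
  }
  peak <- apply(field$strain, 1, max)
  exceed <- if (strict) peak > threshold else peak >= threshold
  .criterion_result(sprintf("CSDM_%g", threshold),
                    sum(field$volume[exceed]) / sum(field$volume), "-",
                    params = list(threshold = threshold, strict = strict))
}

#' Dilatation damage measure (DDM)
#'
#' The fraction of brain volume whose pressure drops below a negative
#' (tension) threshold at any timestep: sum of volumes of elements with
#' minimum pressure below the threshold, divided by the total volume. The
#' conventional threshold is -100 kPa.
#'
#' @param field An [element_field_history()] with pressure populated
#'   (kPa, positive = compression).
#' @param threshold_kPa Negative pressure threshold in kPa. Default -100.
#' @param strict If `TRUE` (default) the comparison is strict (`<`);
#'   an element sitting exactly at the threshold is excluded.
#' @return A `criterion_result` with value in `[0, 1]`.
#' @export
ddm <- function(field, threshold_kPa = -100, strict = TRUE) {
  if (!is.numeric(threshold_kPa) || length(threshold_kPa) != 1 ||
      threshold_kPa >= 0) {
    stop("ddm: threshold must be a negative pressure in kPa", call. = FALSE)
  }
  if (is.null(field$pressure)) {
    stop("ddm: field has no pressure data", call. = FALSE)
  }
  pmin <- apply(field$pressure, 1, min)
  exceed <- if (strict) pmin < threshold_kPa else pmin <= threshold_kPa
  .criterion_result("DDM",
                    sum(field$volume[exceed]) / sum(field$volume), "-",
                    params = list(threshold_kPa = threshold_kPa,
                                  strict = strict))
}

#' Compute all deformation criteria for a field
#'
#' @param field An [element_field_history()].
#' @param csdm_thresholds Strain thresholds for CSDM.
#' @param ddm_threshold Pressure threshold (kPa) for DDM; skipped when the
#'   field carries no pressure data.
#' @return Named list of `criterion_result` objects: MPS, one CSDM per
#'   threshold, and DDM when available.
#' @export
compute_all_deformation <- function(field, csdm_thresholds = c(0.15, 0.25),
                                    ddm_threshold = -100) {
  out <- list(MPS = mps(field))
  for (th in csdm_thresholds) {
    r <- csdm(field, th)
    out[[r$name]] <- r
  }
  if (!is.null(field$pressure)) out$DDM <- ddm(field, ddm_threshold)
  out
}
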