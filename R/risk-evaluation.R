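# ---------------------------------------------------------------------------
# Pearson correlation --------------------------------------------------------

#' Sample Pearson correlation coefficient
#'
#' `r = sum((x - mean(x)) * (y - mean(y))) /
#'      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))`.
#'
#' Implemented directly from the product-moment definition; a constant
#' vector makes the correlation undefined and raises an error rather than
#' silently returning 0 or NA.
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))  # ~0.982
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pearson_r: vectors must have equal length", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("pearson_r: at least 3 observations required", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("pearson_r: missing values not allowed", call. = FALSE)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sx <- sum(dx^2)
  sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    stop("pearson_r: correlation undefined for a constant vector",
         call. = FALSE)
  }
  r <- sum(dx * dy) / sqrt(sx * sy)
  min(1, max(-1, r))
}

# ---------------------------------------------------------------------------
# Criterion-vs-MAIS evaluation ----------------------------------------------

#' Evaluate injury criteria against MAIS by Pearson correlation
#'
#' Joins a per-case criterion table with an injury-record table on
#' `case_id`, computes the Pearson correlation of every criterion column
#' against the MAIS score (treated as a numeric 0-6 scale), and ranks the
#' criteria by decreasing absolute correlation. A rank-correlation option
#' (`method = "spearman"`) is available for sensitivity checks.
#'
#' @param criteria Data frame with `case_id` plus one numeric column per
#'   criterion (e.g. `HIC`, `GAMBIT`, `BrIC`, `RIC`, `HIP`).
#' @param injuries Data frame with `case_id` and `mais` (plus optional
#'   sub-injury AIS columns, ignored here).
#' @param method `"pearson"` (default, the product-moment coefficient
#'   computed by [pearson_r()]) or `"spearman"`.
#' @return An `evaluation_report`: data.frame with columns `criterion`,
#'   `r`, `rank`, plus attribute `n_cases`.
#' @export
evaluate_criteria <- function(criteria, injuries,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!"case_id" %in% names(criteria) || !"case_id" %in% names(injuries)) {
    stop("evaluate_criteria: both tables need a `case_id` column",
         call. = FALSE)
  }
  if (!"mais" %in% names(injuries)) {
    stop("evaluate_criteria: injuries table needs a `mais` column",
         call. = FALSE)
  }
  only_c <- setdiff(criteria$case_id, injuries$case_id)
  only_i <- setdiff(injuries$case_id, criteria$case_id)
  if (length(only_c) || length(only_i)) {
    stop(sprintf(
      "evaluate_criteria: unmatched case ids (criteria only: %s; injuries only: %s)",
      paste(only_c, collapse = ","), paste(only_i, collapse = ",")),
      call. = FALSE)
  }
  if (anyNA(injuries$mais)) {
    stop("evaluate_criteria: MAIS must be recorded for every case",
         call. = FALSE)
  }
  m <- merge(criteria, injuries[, c("case_id", "mais")], by = "case_id",
             sort = FALSE)
  cols <- setdiff(names(criteria), "case_id")
  cols <- cols[vapply(criteria[cols], is.numeric, logical(1))]
  if (!length(cols)) {
    stop("evaluate_criteria: no numeric criterion columns found",
         call. = FALSE)
  }
  r <- vapply(cols, function(cl) {
    if (anyNA(m[[cl]])) {
      stop(sprintf("evaluate_criteria: missing values in column `%s`", cl),
           call. = FALSE)
    }
    if (method == "pearson") {
      pearson_r(m[[cl]], m$mais)
    } else {
      stats::cor(m[[cl]], m$mais, method = "spearman")
    }
  }, numeric(1))
  rep <- data.frame(criterion = cols, r = unname(r),
                    stringsAsFactors = FALSE)
  rep$rank <- rank(-abs(rep$r), ties.method = "min")
  attr(rep, "n_cases") <- nrow(m)
  attr(rep, "method") <- method
  class(rep) <- c("evaluation_report", "data.frame")
  rep
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Criterion-MAIS correlation (%s, n = %d cases)\n",
              attr(x, "method"), attr(x, "n_cases")))
  y <- x[order(x$rank), , drop = FALSE]
  y$r <- sprintf("%.3f", y$r)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Injury risk curves ---------------------------------------------------------

#' Define an injury risk curve
#'
#' A monotone map from a criterion value to an injury probability.
#' Two functional forms are supported:
#'
#' * `logistic`: `p(v) = 1 / (1 + exp(-(intercept + slope * v)))`,
#'   `slope > 0`;
#' * `weibull`: `p(v) = 1 - exp(-((v / scale)^shape))` for `v > 0`, 0
#'   otherwise; `scale, shape > 0`.
#'
#' Parameters are configuration data: risk curves published in the
#' literature come parameterised, and any shipped defaults are labelled
#' approximations.
#'
#' @param criterion Criterion name the curve applies to (e.g. `"CSDM_0.25"`,
#'   `"MPS"`, `"DDM"`).
#' @param injury_type `"DAI"` or `"contusion"`.
#' @param form `"logistic"` or `"weibull"`.
#' @param params Named list of parameters: `intercept`, `slope` for
#'   logistic; `scale`, `shape` for weibull.
#' @return An object of class `risk_curve`.
#' @export
risk_curve <- function(criterion, injury_type = c("DAI", "contusion"),
                       form = c("logistic", "weibull"), params) {
  injury_type <- match.arg(injury_type)
  form <- match.arg(form)
  need <- switch(form, logistic = c("intercept", "slope"),
                 weibull = c("scale", "shape"))
  if (missing(params) || !all(need %in% names(params))) {
    stop(sprintf("risk_curve: %s form requires parameters: %s", form,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  params <- lapply(params[need], as.numeric)
  if (form == "logistic" && params$slope <= 0) {
    stop("risk_curve: logistic slope must be positive (monotone non-decreasing)",
         call. = FALSE)
  }
  if (form == "weibull" && (params$scale <= 0 || params$shape <= 0)) {
    stop("risk_curve: weibull scale and shape must be positive",
         call. = FALSE)
  }
  structure(list(criterion = criterion, injury_type = injury_type,
                 form = form, params = params), class = "risk_curve")
}

#' Injury probability from a risk curve
#'
#' @param curve A [risk_curve()].
#' @param value Criterion value(s).
#' @return Probability vector in `[0, 1]`, monotone non-decreasing in
#'   `value`.
#' @export
risk_probability <- function(curve, value) {
  if (!inherits(curve, "risk_curve")) {
    stop("risk_probability: curve must be a risk_curve (unparameterised curve?)",
         call. = FALSE)
  }
  p <- curve$params
  switch(curve$form,
         logistic = 1 / (1 + exp(-(p$intercept + p$slope * value))),
         weibull = ifelse(value > 0,
                          1 - exp(-((value / p$scale)^p$shape)), 0))
}

#' Read risk curves from a YAML configuration file
#'
#' The file holds a list of entries with fields `criterion`,
#' `injury_type`, `form` and `params`, mirroring [risk_curve()].
#'
#' @param path Path to the YAML file.
#' @return List of `risk_curve` objects.
#' @export
read_risk_curves <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(e) {
    risk_curve(e$criterion, e$injury_type, e$form, e$params)
  })
}

#' Per-case injury-risk report
#'
#' For each requested (criterion, injury type) pair, restricts the cases
#' to those with the relevant AIS recorded, maps the criterion value
#' through the matching risk curve, and tabulates the predicted
#' probability beside the recorded AIS score.
#'
#' @param criteria Data frame with `case_id` and criterion value columns.
#' @param injuries Data frame with `case_id` and AIS columns named
#'   `dai_ais` and/or `contusion_ais` (NA = not recorded).
#' @param curves List of [risk_curve()] objects; must cover every
#'   criterion column / injury type requested.
#' @param pairs Optional data.frame with columns `criterion`,
#'   `injury_type` restricting which combinations to report; defaults to
#'   every curve in `curves` whose criterion column is present.
#' @return Data frame with columns `case_id`, `injury_type`, `ais`,
#'   `criterion`, `value`, `probability`.
#' @export
risk_report <- function(criteria, injuries, curves, pairs = NULL) {
  key <- function(cr, it) paste(cr, it, sep = "/")
  curve_map <- stats::setNames(curves, vapply(curves, function(cv)
    key(cv$criterion, cv$injury_type), character(1)))
  if (is.null(pairs)) {
    pairs <- do.call(rbind, lapply(curves, function(cv)
      data.frame(criterion = cv$criterion, injury_type = cv$injury_type,
                 stringsAsFactors = FALSE)))
    pairs <- pairs[pairs$criterion %in% names(criteria), , drop = FALSE]
  }
  ais_col <- c(DAI = "dai_ais", contusion = "contusion_ais")
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    cr <- pairs$criterion[i]
    it <- pairs$injury_type[i]
    cv <- curve_map[[key(cr, it)]]
    if (is.null(cv)) {
      stop(sprintf("risk_report: no risk curve configured for %s / %s",
                   cr, it), call. = FALSE)
    }
    if (!cr %in% names(criteria)) {
      stop(sprintf("risk_report: criterion column `%s` not in table", cr),
           call. = FALSE)
    }
    m <- merge(criteria[, c("case_id", cr)],
               injuries[, c("case_id", ais_col[[it]])], by = "case_id")
    m <- m[!is.na(m[[ais_col[[it]]]]), , drop = FALSE]
    if (nrow(m)) {
      out[[length(out) + 1]] <- data.frame(
        case_id = m$case_id, injury_type = it, ais = m[[ais_col[[it]]]],
        criterion = cr, value = m[[cr]],
        probability = risk_probability(cv, m[[cr]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
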