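# Packaged cohort tables: file names and md5 checksums recorded at
# packaging time; load_fixture() refuses to serve a modified resource.
.fixture_files <- c(table1 = "table1_accidents.csv",
                    table2 = "table2_injuries.csv",
                    table4 = "table4_criteria.csv",
                    table6 = "table6_dai.csv",
                    table7 = "table7_contusion.csv")

.fixture_md5 <- c(table1 = "7c64e5dbe0f725ed2324854421f470b2",
                  table2 = "716f83e80e9789bb268e4f93947ebca0",
                  table4 = "a0f66e088945525555747d5bc1baf947",
                  table6 = "59abeb7ebfb2bf8149a0b744a0494326",
                  table7 = "1d9738b465b82655159b239c84b8cd67")

# Published correlation coefficients for the 31-case cohort, used only to
# print the comparison column of reproduce_table5().
.published_table5 <- c(HIC = 0.606, GAMBIT = 0.332, BrIC = 0.340,
                       RIC = 0.398, HIP = 0.403)

#' Load a packaged cohort table
#'
#' Returns one of the cohort tables shipped with the package, decoded and
#' typed:
#'
#' * `table1` — accident/case metadata for the 31 vulnerable-road-user
#'   impact cases (VRU anthropometry, vehicle, impact speeds); 31 rows.
#' * `table2` — head injury records: DAI AIS, contusion AIS and MAIS per
#'   case, `-` entries decoded to `NA`; 31 rows. Sub-injury AIS is stored
#'   verbatim (some cases carry a MAIS larger than any recorded
#'   sub-injury, reflecting injuries outside the DAI/contusion pair).
#' * `table4` — the five kinematic criterion values per case (HIC,
#'   GAMBIT, BrIC, RIC, HIP in kW); 31 rows.
#' * `table6` — DAI sub-study: DAI AIS with CSDM_0.15, CSDM_0.25 and MPS;
#'   8 rows.
#' * `table7` — contusion sub-study: contusion AIS with MPS and DDM;
#'   7 rows.
#'
#' Each file's md5 checksum is verified against the value recorded at
#' packaging time.
#'
#' @param table_id One of `"table1"`, `"table2"`, `"table4"`, `"table6"`,
#'   `"table7"`.
#' @return A data.frame.
#' @export
#' @examples
#' inj <- load_fixture("table2")
#' table(inj$mais)
load_fixture <- function(table_id = c("table1", "table2", "table4",
                                      "table6", "table7")) {
  table_id <- match.arg(table_id)
  path <- system.file("extdata", .fixture_files[[table_id]],
                      package = "headcrit", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, unname(.fixture_md5[[table_id]]))) {
    stop(sprintf(
      "load_fixture: checksum mismatch for %s (got %s) - packaged resource corrupted?",
      .fixture_files[[table_id]], md5), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ais_cols <- intersect(c("dai_ais", "contusion_ais", "mais"), names(df))
  for (cl in ais_cols) {
    v <- df[[cl]]
    v[v %in% c("-", "")] <- NA
    df[[cl]] <- as.integer(v)
    if (any(df[[cl]] < 0 | df[[cl]] > 6, na.rm = TRUE)) {
      stop(sprintf("load_fixture: AIS values out of 0-6 range in `%s`", cl),
           call. = FALSE)
    }
  }
  df
}

#' Filter accident cases by documented selection predicates
#'
#' Applies named predicates to a case-metadata table (as returned by
#' `load_fixture("table1")`), preserving row order. Supported predicates:
#'
#' * `vru_type` — character vector of types to keep (`"pedestrian"`,
#'   `"cyclist"`, `"electric_two_wheeler"`);
#' * `gender` — character vector of genders to keep;
#' * `min_vehicle_speed_kmh`, `max_vehicle_speed_kmh` — bounds on the
#'   vehicle impact speed.
#'
#' An empty predicate set returns all cases. The cohort's inclusion
#' criteria (VRU struck by the vehicle, head impact on the front
#' windshield, head injury sustained) are satisfied by every packaged
#' case, so they need no predicate here.
#'
#' @param cases Data frame of accident cases.
#' @param ... Named predicates from the set above.
#' @return The filtered data frame.
#' @export
#' @examples
#' t1 <- load_fixture("table1")
#' nrow(select_cases(t1, vru_type = "pedestrian"))  # 17
select_cases <- function(cases, ...) {
  preds <- list(...)
  known <- c("vru_type", "gender", "min_vehicle_speed_kmh",
             "max_vehicle_speed_kmh")
  unknown <- setdiff(names(preds), known)
  if (length(unknown) || (length(preds) && is.null(names(preds)))) {
    stop(sprintf("select_cases: unknown predicate(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  keep <- rep(TRUE, nrow(cases))
  if (!is.null(preds$vru_type)) keep <- keep & cases$vru_type %in% preds$vru_type
  if (!is.null(preds$gender)) keep <- keep & cases$gender %in% preds$gender
  if (!is.null(preds$min_vehicle_speed_kmh)) {
    keep <- keep & cases$vehicle_speed_kmh >= preds$min_vehicle_speed_kmh
  }
  if (!is.null(preds$max_vehicle_speed_kmh)) {
    keep <- keep & cases$vehicle_speed_kmh <= preds$max_vehicle_speed_kmh
  }
  cases[keep, , drop = FALSE]
}

#' Reproduce the criterion-vs-MAIS correlation table
#'
#' Runs [evaluate_criteria()] on the packaged criterion values (`table4`)
#' and injury records (`table2`) and places the computed Pearson
#' correlations beside the published coefficients for the same cohort,
#' with absolute differences. Deterministic and idempotent.
#'
#' @return A list with `report` (the [evaluate_criteria()] output) and
#'   `comparison` (data.frame: criterion, computed r, published r,
#'   `abs_diff`).
#' @export
#' @examples
#' rt <- reproduce_table5()
#' rt$comparison
reproduce_table5 <- function() {
  criteria <- load_fixture("table4")
  injuries <- load_fixture("table2")
  report <- evaluate_criteria(criteria, injuries)
  computed <- stats::setNames(report$r, report$criterion)
  nm <- names(.published_table5)
  comparison <- data.frame(
    criterion = nm,
    computed_r = unname(computed[nm]),
    published_r = unname(.published_table5),
    stringsAsFactors = FALSE)
  comparison$abs_diff <- abs(comparison$computed_r - comparison$published_r)
  list(report = report, comparison = comparison)
}
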