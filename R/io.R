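# shared CSV machinery: structural validation with line numbers.
# CSV line numbers are data rows + 1 (header).
.read_table <- function(path, required, numeric_cols, optional = character()) {
  if (!file.exists(path))
    pms_stop(paste0("file not found: ", path), "pms_data_format")
  if (file.size(path) == 0)
    pms_stop(paste0("empty input file: ", path), "pms_data_format")
  d <- tryCatch(read.csv(path, stringsAsFactors = FALSE, dec = "."),
                error = function(e)
                  pms_stop(paste0("cannot parse ", path, ": ", conditionMessage(e)),
                           "pms_data_format"))
  if (nrow(d) == 0)
    pms_stop(paste0("no data rows in ", path), "pms_data_format")
  miss <- setdiff(required, names(d))
  if (length(miss))
    pms_stop(paste0(path, " is missing column(s): ", paste(miss, collapse = ", ")),
             "pms_data_format")
  for (col in intersect(c(numeric_cols, optional), names(d))) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "")
    if (length(bad))
      pms_stop(sprintf("%s: non-numeric value in column %s at line(s) %s",
                       path, col, paste(bad + 1L, collapse = ", ")),
               "pms_data_format")
    nas <- which(is.na(v))
    if (col %in% numeric_cols && length(nas))
      pms_stop(sprintf("%s: missing value in column %s at line(s) %s",
                       path, col, paste(nas + 1L, collapse = ", ")),
               "pms_data_format")
    d[[col]] <- v
  }
  d
}

.check_unique_ids <- function(d, path) {
  dup <- unique(d$patient_id[duplicated(d$patient_id)])
  if (length(dup))
    pms_stop(paste0(path, ": duplicate patient_id: ", paste(dup, collapse = ", ")),
             "pms_data_format")
}

.check_map_range <- function(map, path) {
  if (any(map < 30 | map > 150, na.rm = TRUE))
    pms_warn(paste0(path, ": MAP values outside 30-150 mmHg; check units (kPa?)"),
             "pms_unit_warning")
}

#' Read a per-patient cohort CSV
#'
#' Columns: `patient_id`, `age_y`, `height_cm`, `weight_kg`, `rap_mmHg`,
#' `map_mmHg`, `co_lmin` and/or `ci_lminm2`. Decimal point, not comma.
#' Structural problems (missing column, non-numeric cell, duplicate
#' patient_id) raise `pms_data_format` errors naming the offending line;
#' MAP values outside 30-150 mmHg raise a unit-sanity warning.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_cohort_csv <- function(path) {
  d <- .read_table(path,
                   required = c("patient_id", "age_y", "height_cm", "weight_kg",
                                "rap_mmHg", "map_mmHg"),
                   numeric_cols = c("age_y", "height_cm", "weight_kg",
                                    "rap_mmHg", "map_mmHg"),
                   optional = c("co_lmin", "ci_lminm2"))
  if (!any(c("co_lmin", "ci_lminm2") %in% names(d)))
    pms_stop(paste0(path, " needs a co_lmin or ci_lminm2 column"), "pms_data_format")
  .check_unique_ids(d, path)
  .check_map_range(d$map_mmHg, path)
  d
}

#' Read an inspiratory-hold table CSV
#'
#' Columns: `patient_id`, `pplateau_cmh2o`, `rap_mmHg`, `ci_lminm2`
#' (or `co_lmin`), `hold_s`. Column names are normalized to the short
#' names used by [vr_curve()] (`pplateau`, `rap`, `ci`, `co`,
#' `duration`).
#'
#' @param path Path to the CSV file.
#' @return Validated data frame with normalized column names.
#' @export
read_holds_csv <- function(path) {
  d <- .read_table(path,
                   required = c("patient_id", "pplateau_cmh2o", "rap_mmHg", "hold_s"),
                   numeric_cols = c("pplateau_cmh2o", "rap_mmHg", "hold_s"),
                   optional = c("ci_lminm2", "co_lmin"))
  if (!any(c("ci_lminm2", "co_lmin") %in% names(d)))
    pms_stop(paste0(path, " needs a ci_lminm2 or co_lmin column"), "pms_data_format")
  ren <- c(pplateau_cmh2o = "pplateau", rap_mmHg = "rap", ci_lminm2 = "ci",
           co_lmin = "co", hold_s = "duration")
  names(d) <- ifelse(names(d) %in% names(ren), ren[names(d)], names(d))
  d
}

#' Read a paired study-record CSV
#'
#' Columns: `patient_id`, `pmsa_mmHg`, `pms_insp_mmHg`, `vasopressor`
#' (0/1). Names are normalized for [run_study()].
#'
#' @param path Path to the CSV file.
#' @return Validated data frame with columns `patient_id`, `pmsa`,
#'   `pms_insp`, `vasopressor` (logical).
#' @export
read_pairs_csv <- function(path) {
  d <- .read_table(path,
                   required = c("patient_id", "pmsa_mmHg", "pms_insp_mmHg"),
                   numeric_cols = c("pmsa_mmHg", "pms_insp_mmHg"),
                   optional = "vasopressor")
  .check_unique_ids(d, path)
  out <- data.frame(patient_id = d$patient_id, pmsa = d$pmsa_mmHg,
                    pms_insp = d$pms_insp_mmHg)
  if ("vasopressor" %in% names(d)) out$vasopressor <- d$vasopressor != 0
  out
}

#' Read a monitor stream CSV
#'
#' Columns: `time_s`, `rap_mmHg`, `map_mmHg`, `co_lmin`; normalized to
#' `time`, `rap`, `map`, `co` for [pmsa_realtime()] and
#' [extract_hold_values()].
#'
#' @param path Path to the CSV file.
#' @return Validated stream data frame.
#' @export
read_stream_csv <- function(path) {
  d <- .read_table(path,
                   required = c("time_s", "rap_mmHg", "map_mmHg", "co_lmin"),
                   numeric_cols = c("time_s", "rap_mmHg", "map_mmHg", "co_lmin"))
  if (is.unsorted(d$time_s))
    pms_stop(paste0(path, ": time_s must be nondecreasing"), "pms_data_format")
  .check_map_range(d$map_mmHg, path)
  setNames(d, c("time", "rap", "map", "co"))
}

#' Write simulator outputs in the consumed CSV dialects
#'
#' Writes a simulated cohort as the pairs CSV (plus a truth CSV) so that
#' the files round-trip through [read_pairs_csv()].
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pairs_path <- file.path(dir, "pairs.csv")
  truth_path <- file.path(dir, "truth.csv")
  write.csv(data.frame(patient_id = cohort$patient_id,
                       pmsa_mmHg = cohort$pmsa,
                       pms_insp_mmHg = cohort$pms_insp,
                       vasopressor = as.integer(cohort$vasopressor)),
            pairs_path, row.names = FALSE, quote = FALSE)
  write.csv(cohort, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(pairs = pairs_path, truth = truth_path))
}

# strip non-serializable pieces (lm fits, closures) for JSON output
.report_payload <- function(x) {
  if (inherits(x, "lm")) return(NULL)
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(unclass(x), .report_payload)
    return(x[!vapply(x, is.null, TRUE)])
  }
  x
}

#' Write a machine-readable study report
#'
#' Serializes a report (e.g. from [pms_report()] or [run_study()]) to
#' JSON. Every report embeds the package version, the resolved
#' configuration and the seed, so a written report identifies the run
#' that produced it; output is byte-stable for a fixed seed.
#'
#' @param report The report object.
#' @param path Output path (`.json`).
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(.report_payload(report), path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  invisible(path)
}
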