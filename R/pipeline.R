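#' End-to-end study report
#'
#' Runs the whole pipeline — analogue Pmsa computation, venous-return-curve
#' fitting per patient, and the method-agreement study — from either
#' recorded tables or the built-in simulator, and returns a reproducible
#' report embedding the package version, the resolved configuration and
#' the seed.
#'
#' Three input modes:
#' \describe{
#'   \item{simulate}{`simulate = sim_config(...)` (or `"default"`):
#'     generates a virtual cohort with known truth and compares the two
#'     estimates against each other (and records truth summaries).}
#'   \item{pairs}{`pairs`: a precomputed paired table (columns `pmsa`,
#'     `pms_insp`, optional `vasopressor`).}
#'   \item{cohort + holds}{a per-patient snapshot table and a hold table;
#'     Pmsa is computed from the snapshot, Pms-Insp fitted per patient
#'     from its holds, and the two joined on `patient_id`. A `vasopressor`
#'     column on the cohort table stratifies the analysis.}
#' }
#'
#' @param pairs Optional paired data frame (see [run_study()]).
#' @param cohort Optional per-patient snapshot table (see
#'   [read_cohort_csv()] for the schema).
#' @param holds Optional hold table (see [read_holds_csv()]).
#' @param simulate Optional [sim_config()] or the string `"default"`.
#' @param seed Seed overriding `simulate$seed` when given.
#' @param flow Flow axis for curve fitting, `"ci"` or `"co"`.
#' @param cov_definition Passed to [run_study()].
#' @param out Optional path; when given the report is written as JSON via
#'   [write_report()].
#' @return Object of class `pms_report`: list with `version`, `seed`,
#'   `config`, `stages` (log of executed stages), `study` (the
#'   [run_study()] result) and, in simulation mode, `truth_summary`.
#' @export
pms_report <- function(pairs = NULL, cohort = NULL, holds = NULL,
                       simulate = NULL, seed = NULL, flow = c("ci", "co"),
                       cov_definition = "diff_sd_over_mean", out = NULL) {
  flow <- match.arg(flow)
  stages <- character()
  log_stage <- function(s) stages <<- c(stages, s)
  truth_summary <- NULL
  config <- NULL
  if (!is.null(simulate)) {
    config <- if (identical(simulate, "default")) sim_config() else simulate
    if (!inherits(config, "sim_config"))
      pms_stop("simulate must be a sim_config or \"default\"", "pms_invalid_argument")
    if (!is.null(seed)) config$seed <- as.integer(seed)
    log_stage(sprintf("simulate: cohort of %d virtual patients (seed %d)",
                      config$cohort_size, config$seed))
    sim <- simulate_cohort(config)
    pairs <- sim[, c("patient_id", "pmsa", "pms_insp", "vasopressor")]
    truth_summary <- list(
      mean_pms_true = mean(sim$pms_true),
      mean_error_pmsa = mean(sim$pmsa - sim$pms_true),
      mean_error_pms_insp = mean(sim$pms_insp - sim$pms_true))
  } else if (!is.null(cohort) && !is.null(holds)) {
    log_stage("compute: Pmsa per patient from snapshot table")
    scored <- pmsa_cohort(cohort)
    log_stage("vr-fit: venous return curve per patient")
    ids <- unique(holds$patient_id)
    fits <- lapply(ids, function(id)
      vr_curve(holds[holds$patient_id == id, , drop = FALSE], flow = flow))
    pi <- data.frame(patient_id = ids,
                     pms_insp = vapply(fits, `[[`, 0, "pms_insp"))
    pairs <- merge(data.frame(patient_id = scored$patient_id,
                              pmsa = scored$pmsa_mmHg),
                   pi, by = "patient_id")
    if ("vasopressor" %in% names(cohort))
      pairs <- merge(pairs, cohort[, c("patient_id", "vasopressor")],
                     by = "patient_id")
    if (nrow(pairs) == 0)
      pms_stop("no patient_id overlap between cohort and holds tables",
               "pms_data_format")
  } else if (is.null(pairs)) {
    pms_stop("provide pairs, cohort + holds, or simulate", "pms_invalid_argument")
  }
  log_stage("agree: method-agreement statistics")
  study <- run_study(pairs, cov_definition = cov_definition)
  report <- structure(list(
    version = as.character(packageVersion("pmsagree")),
    seed = if (!is.null(config)) config$seed else seed,
    config = if (!is.null(config)) unclass(config) else
      list(flow = flow, cov_definition = cov_definition),
    stages = stages,
    truth_summary = truth_summary,
    study = study), class = "pms_report")
  if (!is.null(out)) {
    write_report(report, out)
    log_stage(paste("write:", out))
  }
  report
}

#' @export
print.pms_report <- function(x, ...) {
  cat("pmsagree study report (version ", x$version,
      if (!is.null(x$seed)) paste0(", seed ", x$seed), ")\n", sep = "")
  for (s in x$stages) cat("  *", s, "\n")
  if (!is.null(x$truth_summary))
    cat(sprintf("  simulator truth: mean Pms %.2f mmHg; mean error Pmsa %+.3f, Pms-Insp %+.3f\n",
                x$truth_summary$mean_pms_true, x$truth_summary$mean_error_pmsa,
                x$truth_summary$mean_error_pms_insp))
  cat("\n")
  print(x$study)
  invisible(x)
}
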