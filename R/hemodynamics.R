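#' Du Bois body surface area
#'
#' Computes body surface area from height and weight with the Du Bois
#' formula, `0.007184 * height^0.725 * weight^0.425`.
#'
#' @param height_cm Height in centimetres (> 0). Vectorized.
#' @param weight_kg Body weight in kilograms (> 0). Vectorized.
#' @return Body surface area in square metres.
#' @examples
#' du_bois_bsa(176, 86)  # about 2.03 m^2
#' @export
du_bois_bsa <- function(height_cm, weight_kg) {
  if (!is.numeric(height_cm) || !is.numeric(weight_kg))
    pms_stop("height and weight must be numeric", "pms_invalid_argument")
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0))
    pms_stop("height and weight must be finite and positive", "pms_invalid_argument")
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Anthropometric constant of the Pmsa algorithm
#'
#' The constant `c` (mmHg.min/L) that scales cardiac output in the analogue
#' mean systemic filling pressure:
#' `c = 0.038 * (94.17 + 0.193*age) / (4.5 * 0.99^(age-15) * BSA)`,
#' with BSA the Du Bois body surface area. It bundles an age-dependent
#' vascular-resistance term with body size; larger patients get a smaller
#' constant.
#'
#' @param age_y Age in years, >= 15 (the age-decay exponent is anchored at
#'   15; younger ages are outside the formula's provenance and rejected).
#'   Fractional years are accepted.
#' @param height_cm Height in centimetres (> 0).
#' @param weight_kg Body weight in kilograms (> 0).
#' @return The constant `c` in mmHg.min/L.
#' @examples
#' anthropometric_constant(63, 176, 86)  # about 0.72
#' @export
anthropometric_constant <- function(age_y, height_cm, weight_kg) {
  if (!is.numeric(age_y) || any(!is.finite(age_y)))
    pms_stop("age must be finite numeric", "pms_invalid_argument")
  if (any(age_y < 15))
    pms_stop("age below 15 years is outside the domain of the Pmsa constant",
             "pms_domain_error")
  bsa <- du_bois_bsa(height_cm, weight_kg)
  0.038 * (94.17 + 0.193 * age_y) / (4.5 * 0.99^(age_y - 15) * bsa)
}

#' Analogue mean systemic filling pressure (Pmsa)
#'
#' Parkin's bedside analogue of mean systemic filling pressure from a
#' single hemodynamic snapshot:
#' `Pmsa = 0.96*RAP + 0.04*MAP + c*CO`.
#' The pressure weights sum to one, so at zero flow with RAP = MAP the
#' analogue equals that common pressure.
#'
#' @param rap Right atrial pressure, mmHg.
#' @param map Mean arterial pressure, mmHg.
#' @param co Cardiac output, L/min (not mL/min and not indexed; the
#'   constant `c` is scaled for L/min and yields Pmsa near 11 mmHg at
#'   typical adult values).
#' @param c Anthropometric constant from [anthropometric_constant()],
#'   mmHg.min/L, > 0.
#' @return Pmsa in mmHg (vectorized over the inputs).
#' @seealso [pvr()] for the venous-return pressure gradient,
#'   [pmsa_cohort()] for tabular input, [pmsa_realtime()] for streams.
#' @examples
#' cc <- anthropometric_constant(63, 176, 86)
#' pmsa(rap = 4.4, map = 69, co = 5.35, c = cc)
#' @export
pmsa <- function(rap, map, co, c) {
  for (v in list(rap, map, co, c))
    if (!is.numeric(v) || length(v) == 0 || any(!is.finite(v)))
      pms_stop("rap, map, co and c must all be finite numerics",
               "pms_invalid_argument")
  if (any(co < 0)) pms_stop("cardiac output must be >= 0", "pms_invalid_argument")
  if (any(c <= 0)) pms_stop("anthropometric constant must be > 0", "pms_invalid_argument")
  0.96 * rap + 0.04 * map + c * co
}

#' Pressure gradient for venous return
#'
#' The driving pressure of venous return, `pVR = Pms - RAP`.
#'
#' @param pms Mean systemic filling pressure (either estimate), mmHg.
#' @param rap Right atrial pressure, mmHg.
#' @return pVR in mmHg.
#' @export
pvr <- function(pms, rap) pms - rap

#' Pmsa for a cohort table
#'
#' Applies the Pmsa algorithm to a per-patient table (the schema written by
#' [read_cohort_csv()]): computes body surface area, the anthropometric
#' constant, Pmsa and pVR per row. When both `co_lmin` and `ci_lminm2` are
#' present, their consistency (`co ~ ci * bsa`) is validated within
#' `ci_co_tol`; when only CI is present, CO is derived as `ci * bsa`.
#'
#' @param cohort Data frame with columns `patient_id`, `age_y`, `height_cm`,
#'   `weight_kg`, `rap_mmHg`, `map_mmHg`, and `co_lmin` and/or `ci_lminm2`.
#' @param ci_co_tol Relative tolerance for the CO vs CI x BSA cross-check
#'   (default 0.05, i.e. 5%).
#' @return The input data frame with columns `bsa_m2`, `c_const`,
#'   `pmsa_mmHg` and `pvr_mmHg` appended.
#' @export
pmsa_cohort <- function(cohort, ci_co_tol = 0.05) {
  need <- c("patient_id", "age_y", "height_cm", "weight_kg", "rap_mmHg", "map_mmHg")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    pms_stop(paste("cohort is missing columns:", paste(miss, collapse = ", ")),
             "pms_data_format")
  has_co <- "co_lmin" %in% names(cohort)
  has_ci <- "ci_lminm2" %in% names(cohort)
  if (!has_co && !has_ci)
    pms_stop("cohort needs co_lmin or ci_lminm2", "pms_data_format")
  bsa <- du_bois_bsa(cohort$height_cm, cohort$weight_kg)
  co <- if (has_co) cohort$co_lmin else cohort$ci_lminm2 * bsa
  if (has_co && has_ci) {
    rel <- abs(cohort$co_lmin - cohort$ci_lminm2 * bsa) / pmax(cohort$co_lmin, 1e-12)
    bad <- which(is.finite(rel) & rel > ci_co_tol)
    if (length(bad))
      pms_warn(paste0("CO and CI x BSA disagree by more than ",
                      round(100 * ci_co_tol), "% for patient(s): ",
                      paste(cohort$patient_id[bad], collapse = ", ")),
               "pms_unit_warning")
  }
  cc <- anthropometric_constant(cohort$age_y, cohort$height_cm, cohort$weight_kg)
  p <- pmsa(cohort$rap_mmHg, cohort$map_mmHg, co, cc)
  cohort$bsa_m2 <- bsa
  cohort$c_const <- cc
  cohort$pmsa_mmHg <- p
  cohort$pvr_mmHg <- pvr(p, cohort$rap_mmHg)
  cohort
}

#' Realtime Pmsa over a monitor stream
#'
#' Computes per-sample Pmsa from synchronized RAP/MAP/CO channels and
#' smooths it with a trailing mean, emulating a bedside monitor. The value
#' used for comparison with an inspiratory-hold estimate is the smoothed
#' value at the last sample before the hold starts (see
#' [pmsa_before_holds()]).
#'
#' @param stream Data frame with numeric columns `time`, `rap`, `map`, `co`
#'   (seconds, mmHg, mmHg, L/min), equal-length and time-sorted, e.g. from
#'   [read_stream_csv()] or [simulate_holds()].
#' @param c Anthropometric constant, mmHg.min/L.
#' @param window Trailing smoothing window in seconds (default 30).
#' @return Data frame `time`, `pmsa` (smoothed), `pmsa_raw`.
#' @export
pmsa_realtime <- function(stream, c, window = 30) {
  need <- c("time", "rap", "map", "co")
  if (!is.data.frame(stream) || !all(need %in% names(stream)))
    pms_stop("stream needs columns time, rap, map, co", "pms_data_format")
  if (nrow(stream) == 0)
    pms_stop("empty monitor stream", "pms_data_format")
  lens <- vapply(stream[need], function(x) sum(is.finite(x)), 0L)
  if (length(unique(lens)) != 1L || any(!is.finite(as.matrix(stream[need]))))
    pms_stop("stream channels are unsynchronized (unequal finite lengths)",
             "pms_data_format")
  raw <- pmsa(stream$rap, stream$map, stream$co, c)
  t <- stream$time
  # trailing mean over (t - window, t]; O(n) two-pointer sweep
  sm <- numeric(length(raw))
  cs <- cumsum(raw)
  lo <- 1L
  for (i in seq_along(raw)) {
    while (t[lo] <= t[i] - window) lo <- lo + 1L
    sm[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  data.frame(time = t, pmsa = sm, pmsa_raw = raw)
}

#' Pre-hold Pmsa values
#'
#' Extracts, for each tagged inspiratory-hold window, the smoothed Pmsa at
#' the last sample strictly before the hold begins.
#'
#' @param rt Result of [pmsa_realtime()].
#' @param windows Data frame of hold windows with columns `start`, `end`
#'   (seconds) and optionally `pplateau`.
#' @return Data frame with one row per window: `pplateau` (if given),
#'   `start`, `pmsa`.
#' @export
pmsa_before_holds <- function(rt, windows) {
  if (!all(c("start", "end") %in% names(windows)))
    pms_stop("windows need start and end columns", "pms_data_format")
  idx <- vapply(windows$start, function(s) {
    i <- which(rt$time < s)
    if (!length(i)) NA_integer_ else max(i)
  }, 0L)
  if (any(is.na(idx)))
    pms_stop("a hold window starts before the stream does", "pms_data_format")
  out <- data.frame(start = windows$start, pmsa = rt$pmsa[idx])
  if ("pplateau" %in% names(windows)) out <- cbind(pplateau = windows$pplateau, out)
  out
}
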