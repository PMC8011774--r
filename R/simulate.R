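#' Simulation configuration
#'
#' Bundles and validates the settings of the virtual-patient simulator:
#' the inspiratory-hold schedule and the measurement-noise model of the
#' emulated monitors.
#'
#' Noise is additive Gaussian on pressures and multiplicative lognormal
#' (mean-preserving) on cardiac output, specified per monitor sample;
#' hold-level read-outs average `hold_tail * sample_rate` samples, so
#' their effective noise shrinks accordingly, exactly as a 3-s read-out
#' of a real monitor trace would.
#'
#' @param hold_schedule Airway plateau pressures, cm H2O.
#' @param hold_duration Hold length, seconds (>= 12 per protocol).
#' @param hold_tail Averaged read-out tail, seconds.
#' @param interval_s Baseline interval between holds, seconds.
#' @param noise_sd_rap,noise_sd_map Per-sample additive noise SD, mmHg.
#' @param noise_co_cv Per-sample multiplicative CO noise, coefficient of
#'   variation (fraction).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @param cohort_size Number of virtual patients.
#' @param sample_rate Monitor sampling rate, Hz.
#' @param settling_tau Exponential settling time constant at hold onset,
#'   seconds (streams only).
#' @param transmission_range Range of the airway-to-RAP pressure
#'   transmission fraction drawn per patient.
#' @param rvr_mismatch_sd SD of the per-patient deviation of the
#'   resistance to venous return from the Parkin identity
#'   `RVR = c + 0.04*SVR` (mmHg.min/L); 0 makes Pmsa exactly unbiased.
#' @param flow Flow axis emitted for curve fitting, `"ci"` or `"co"`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(hold_schedule = c(5, 10, 15, 20, 25, 30),
                       hold_duration = 12, hold_tail = 3, interval_s = 120,
                       noise_sd_rap = 0.5, noise_sd_map = 1.0,
                       noise_co_cv = 0.05, seed = 1L, cohort_size = 18L,
                       sample_rate = 1, settling_tau = 1.5,
                       transmission_range = c(0.35, 0.55),
                       rvr_mismatch_sd = 0, flow = c("ci", "co")) {
  flow <- match.arg(flow)
  if (any(c(noise_sd_rap, noise_sd_map, noise_co_cv, rvr_mismatch_sd) < 0))
    pms_stop("noise parameters must be >= 0", "pms_invalid_argument")
  if (hold_duration < 12)
    pms_stop("protocol requires holds of at least 12 s", "pms_protocol_violation")
  if (cohort_size < 1 || sample_rate <= 0 || hold_tail <= 0)
    pms_stop("cohort_size >= 1, sample_rate > 0 and hold_tail > 0 required",
             "pms_invalid_argument")
  structure(list(hold_schedule = hold_schedule, hold_duration = hold_duration,
                 hold_tail = hold_tail, interval_s = interval_s,
                 noise_sd_rap = noise_sd_rap, noise_sd_map = noise_sd_map,
                 noise_co_cv = noise_co_cv, seed = as.integer(seed),
                 cohort_size = as.integer(cohort_size),
                 sample_rate = sample_rate, settling_tau = settling_tau,
                 transmission_range = transmission_range,
                 rvr_mismatch_sd = rvr_mismatch_sd, flow = flow),
            class = "sim_config")
}

#' Construct a virtual patient
#'
#' A Guytonian virtual circulation defined by a venous return line
#' `CO = (Pms - RAP) / RVR` and a saturating cardiac function curve
#' `CO = cf_max * (1 - exp(-cf_slope * (RAP - cf_rap0) / cf_max))`.
#' The patient is parameterized by its baseline operating point
#' (`rap0`, cardiac index `ci0`), systemic vascular resistance, and the
#' local slope of the cardiac function curve at that operating point
#' (the Starling slope); the true mean systemic filling pressure follows
#' as `pms_true = rap0 + rvr * co0`.
#'
#' Unless `rvr` is supplied, the resistance to venous return is set to
#' `c + 0.04 * svr` (with `c` the patient's anthropometric constant), the
#' identity under which the Pmsa algorithm is exactly unbiased at steady
#' state.
#'
#' @param age_y,height_cm,weight_kg Anthropometrics.
#' @param rap0 Baseline right atrial pressure, mmHg.
#' @param ci0 Baseline cardiac index, L/min/m2.
#' @param svr Systemic vascular resistance, mmHg.min/L.
#' @param starling_slope Local slope of the cardiac function curve at the
#'   operating point, L/min per mmHg.
#' @param transmission Fraction of airway plateau pressure transmitted to
#'   RAP, in (0, 1].
#' @param rvr Resistance to venous return, mmHg.min/L; default
#'   `c + 0.04 * svr`.
#' @param cf_headroom Ratio of `cf_max` to baseline CO (> 1).
#' @param cf_shape `"saturating"` (default) or `"linear"` (cardiac
#'   function `CO = starling_slope * (RAP - rap_offset)` through the
#'   origin; used for closed-form checks).
#' @return A list of class `virtual_patient` including the derived
#'   `pms_true`, `rvr`, `co0`, `map0`, `bsa` and `c_const`.
#' @export
virtual_patient <- function(age_y, height_cm, weight_kg, rap0 = 5, ci0 = 2.65,
                            svr = 12, starling_slope = 1.5, transmission = 0.45,
                            rvr = NULL, cf_headroom = 1.6,
                            cf_shape = c("saturating", "linear")) {
  cf_shape <- match.arg(cf_shape)
  bsa <- du_bois_bsa(height_cm, weight_kg)
  cc <- anthropometric_constant(age_y, height_cm, weight_kg)
  co0 <- ci0 * bsa
  rvr <- rvr %||% (cc + 0.04 * svr)
  pms_true <- rap0 + rvr * co0
  if (pms_true <= 0 || rvr <= 0)
    pms_stop("virtual patient needs pms_true > 0 and rvr > 0", "pms_invalid_argument")
  if (svr <= rvr)
    pms_stop("systemic vascular resistance must exceed resistance to venous return",
             "pms_invalid_argument")
  if (transmission <= 0 || transmission > 1)
    pms_stop("transmission fraction must be in (0, 1]", "pms_invalid_argument")
  if (cf_shape == "saturating") {
    cf_max <- cf_headroom * co0
    # choose curve passing through (rap0, co0) with the requested local slope:
    # slope there is cf_slope * (1 - co0/cf_max)
    cf_slope <- starling_slope * cf_max / (cf_max - co0)
    cf_rap0 <- rap0 + (cf_max / cf_slope) * log(1 - co0 / cf_max)
  } else {
    cf_max <- Inf
    cf_slope <- starling_slope
    cf_rap0 <- rap0 - co0 / starling_slope  # line through (rap0, co0)
  }
  structure(list(age_y = age_y, height_cm = height_cm, weight_kg = weight_kg,
                 bsa = bsa, c_const = cc, rap0 = rap0, ci0 = ci0, co0 = co0,
                 svr = svr, rvr = rvr, pms_true = pms_true,
                 map0 = rap0 + co0 * svr, transmission = transmission,
                 starling_slope = starling_slope,
                 cf_shape = cf_shape, cf_slope = cf_slope, cf_max = cf_max,
                 cf_rap0 = cf_rap0),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("Virtual patient: %g y, %g cm, %g kg (BSA %.2f m2)\n",
              x$age_y, x$height_cm, x$weight_kg, x$bsa))
  cat(sprintf("  true Pms %.2f mmHg | RVR %.3f, SVR %.1f mmHg.min/L | c %.3f\n",
              x$pms_true, x$rvr, x$svr, x$c_const))
  cat(sprintf("  baseline: RAP %.1f, MAP %.1f mmHg, CO %.2f L/min (CI %.2f)\n",
              x$rap0, x$map0, x$co0, x$ci0))
  invisible(x)
}

# cardiac function curve: flow as a function of (effective) RAP
.cardiac_function <- function(patient, rap) {
  x <- rap - patient$cf_rap0
  if (patient$cf_shape == "linear")
    return(pmax(0, patient$cf_slope * x))
  ifelse(x <= 0, 0,
         patient$cf_max * (1 - exp(-patient$cf_slope * x / patient$cf_max)))
}

#' Steady-state operating point of a virtual circulation
#'
#' Solves the intersection of the venous return line
#' `CO = (pms_true - RAP) / RVR` with the cardiac function curve shifted
#' right by `rap_offset` (the transmitted airway pressure): in steady
#' state venous return determines cardiac output. MAP follows as
#' `RAP + CO * SVR`.
#'
#' @param patient A [virtual_patient()].
#' @param rap_offset Rightward shift of the cardiac function curve, mmHg
#'   (transmitted plateau pressure; 0 at baseline).
#' @param co_min Flows below this are treated as circulatory collapse.
#' @return List `rap`, `co`, `ci`, `map` (mmHg, L/min, L/min/m2, mmHg).
#' @section Errors: if the curves no longer intersect at positive flow
#'   (effective heart curve pushed beyond `pms_true`),
#'   `pms_circulatory_collapse` is raised.
#' @export
steady_state <- function(patient, rap_offset = 0, co_min = 1e-9) {
  p <- patient
  if (p$cf_shape == "linear") {
    # (pms - rap)/rvr = s*(rap - cf_rap0 - offset)
    s <- p$cf_slope
    rap <- (p$pms_true + p$rvr * s * (p$cf_rap0 + rap_offset)) / (1 + p$rvr * s)
  } else {
    lo <- p$cf_rap0 + rap_offset
    if (lo >= p$pms_true)
      pms_stop("cardiac function curve pushed beyond Pms: circulatory collapse",
               "pms_circulatory_collapse")
    f <- function(r) (p$pms_true - r) / p$rvr - .cardiac_function(p, r - rap_offset)
    rap <- uniroot(f, c(lo, p$pms_true), tol = 1e-10)$root
  }
  co <- (p$pms_true - rap) / p$rvr
  if (co < co_min)
    pms_stop("zero-flow steady state: circulatory collapse", "pms_circulatory_collapse")
  list(rap = rap, co = co, ci = co / p$bsa, map = rap + co * p$svr)
}

# mean-preserving lognormal multiplicative noise with coefficient of
# variation cv (0 -> exact)
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -s^2 / 2, s))
}

#' Simulate an inspiratory-hold sequence
#'
#' Runs the hold schedule on a virtual patient: each plateau pressure P
#' (cm H2O) shifts the cardiac function curve by
#' `transmission * P * 0.7355` mmHg, moving the operating point up the
#' true venous return line, so the noiseless hold points are exactly
#' collinear with x-intercept `pms_true`. Hold-level measurement noise is
#' the average of per-sample monitor noise over the read-out tail.
#' Plateaus that collapse the circulation are excluded and flagged.
#'
#' @param patient A [virtual_patient()].
#' @param config A [sim_config()].
#' @param seed Optional seed set before drawing noise; `NULL` (default)
#'   uses the ambient RNG state (so cohort-level seeding governs).
#' @param emit_stream If `TRUE`, also return a tagged monitor stream
#'   (attribute `"stream"`, with hold windows in attribute `"windows"`):
#'   baseline intervals and holds with exponential settling and
#'   per-sample noise.
#' @return Data frame of hold measurements (`pplateau`, `rap`, `co`,
#'   `ci`, `duration`) with attributes `truth` (noiseless operating
#'   points and `pms_true`) and `findings`.
#' @export
simulate_holds <- function(patient, config = sim_config(), seed = NULL,
                           emit_stream = FALSE) {
  if (!inherits(config, "sim_config"))
    pms_stop("config must be a sim_config", "pms_invalid_argument")
  if (!is.null(seed)) set.seed(seed)
  n_avg <- max(1L, round(config$hold_tail * config$sample_rate))
  rows <- list(); truth <- list(); findings <- character()
  for (P in config$hold_schedule) {
    offset <- patient$transmission * P * CMH2O_TO_MMHG
    ss <- tryCatch(steady_state(patient, offset),
                   pms_circulatory_collapse = function(e) NULL)
    if (is.null(ss)) {
      findings <- c(findings, sprintf(
        "plateau %g cm H2O excluded: circulatory collapse", P))
      next
    }
    rap_m <- ss$rap + rnorm(1, 0, config$noise_sd_rap / sqrt(n_avg))
    co_m <- ss$co * .lognoise(1, config$noise_co_cv / sqrt(n_avg))
    rows[[length(rows) + 1L]] <- data.frame(
      pplateau = P, rap = rap_m, co = co_m, ci = co_m / patient$bsa,
      duration = config$hold_duration)
    truth[[length(truth) + 1L]] <- data.frame(
      pplateau = P, rap = ss$rap, co = ss$co, ci = ss$ci, map = ss$map)
  }
  if (!length(rows))
    pms_stop("every plateau collapsed the circulation", "pms_circulatory_collapse")
  holds <- do.call(rbind, rows)
  attr(holds, "truth") <- list(points = do.call(rbind, truth),
                               pms_true = patient$pms_true, rvr = patient$rvr)
  attr(holds, "findings") <- findings
  if (emit_stream) {
    st <- .emit_stream(patient, config, do.call(rbind, truth))
    attr(holds, "stream") <- st$stream
    attr(holds, "windows") <- st$windows
  }
  holds
}

# tagged monitor stream: baseline interval then hold, exponential settling
.emit_stream <- function(patient, config, truth_points) {
  base <- steady_state(patient, 0)
  dt <- 1 / config$sample_rate
  t_cur <- 0
  seg <- function(from, to, dur) {
    tt <- seq(dt, dur, by = dt)
    w <- exp(-tt / config$settling_tau)
    list(t = t_cur + tt,
         rap = to$rap + (from$rap - to$rap) * w,
         map = to$map + (from$map - to$map) * w,
         co = to$co + (from$co - to$co) * w)
  }
  chunks <- list(); windows <- list()
  state <- base
  for (i in seq_len(nrow(truth_points))) {
    hold <- as.list(truth_points[i, c("rap", "map", "co")])
    s1 <- seg(state, base, config$interval_s); t_cur <- max(s1$t)
    s2 <- seg(base, hold, config$hold_duration)
    windows[[i]] <- data.frame(start = t_cur, end = max(s2$t),
                               pplateau = truth_points$pplateau[i])
    t_cur <- max(s2$t)
    chunks[[2 * i - 1]] <- s1; chunks[[2 * i]] <- s2
    state <- hold
  }
  tt <- unlist(lapply(chunks, `[[`, "t"))
  n <- length(tt)
  stream <- data.frame(
    time = tt,
    rap = unlist(lapply(chunks, `[[`, "rap")) + rnorm(n, 0, config$noise_sd_rap),
    map = unlist(lapply(chunks, `[[`, "map")) + rnorm(n, 0, config$noise_sd_map),
    co = unlist(lapply(chunks, `[[`, "co")) * .lognoise(n, config$noise_co_cv))
  list(stream = stream, windows = do.call(rbind, windows))
}

# cohort-level parameter draws; ranges chosen to reproduce the marginal
# distributions of a post-cardiac-surgery ICU cohort (see methods vignette)
.draw_patient <- function(config) {
  virtual_patient(
    age_y = sample(35:78, 1),
    height_cm = runif(1, 156, 191),
    weight_kg = runif(1, 61, 110),
    rap0 = runif(1, 3, 7),
    ci0 = runif(1, 2.2, 3.4),
    svr = runif(1, 9, 15),
    starling_slope = runif(1, 1.2, 2.0),
    transmission = runif(1, config$transmission_range[1], config$transmission_range[2]),
    rvr = NULL)
}

#' Simulate a paired method-comparison cohort
#'
#' Draws a cohort of virtual patients, measures each one with both
#' methods — the analogue Pmsa from noisy pre-hold monitor values
#' (averaged over the realtime window) and Pms-Insp from a venous return
#' curve fitted to the simulated hold sequence — and returns the paired
#' records together with the ground truth.
#'
#' When `rvr_mismatch_sd = 0` (default) each patient satisfies
#' `RVR = c + 0.04 * SVR`, under which Pmsa equals the true Pms exactly
#' at zero noise; a nonzero mismatch injects a controlled, known-sign
#' method bias.
#'
#' @param config A [sim_config()]; `config$seed` makes the cohort
#'   bit-reproducible.
#' @param realtime_window Averaging window of the emulated Pmsa monitor,
#'   seconds.
#' @return Data frame of class `pms_cohort` with columns `patient_id`,
#'   `pmsa`, `pms_insp`, `vasopressor`, the anthropometrics, and truth
#'   columns (`pms_true`, `rvr`, `svr`, `c_const`, `bsa`, `rap0`, `co0`,
#'   `transmission`); the config is attached as attribute `"config"`.
#' @export
simulate_cohort <- function(config = sim_config(), realtime_window = 30) {
  if (!inherits(config, "sim_config"))
    pms_stop("config must be a sim_config", "pms_invalid_argument")
  set.seed(config$seed)
  n_rt <- max(1L, round(realtime_window * config$sample_rate))
  rows <- list()
  redraws <- 0L
  for (i in seq_len(config$cohort_size)) {
    # a patient whose hold sequence is unusable (circulatory collapse on
    # most plateaus, or a degenerate curve) could not have been studied;
    # redraw, emulating eligibility
    for (attempt in 1:25) {
      p <- .draw_patient(config)
      if (config$rvr_mismatch_sd > 0) {
        rvr <- p$rvr + rnorm(1, 0, config$rvr_mismatch_sd)
        p <- virtual_patient(p$age_y, p$height_cm, p$weight_kg, p$rap0, p$ci0,
                             p$svr, starling_slope = p$starling_slope,
                             transmission = p$transmission, rvr = max(rvr, 0.2))
      }
      res <- tryCatch({
        base <- steady_state(p, 0)
        rap_m <- base$rap + rnorm(1, 0, config$noise_sd_rap / sqrt(n_rt))
        map_m <- base$map + rnorm(1, 0, config$noise_sd_map / sqrt(n_rt))
        co_m <- base$co * .lognoise(1, config$noise_co_cv / sqrt(n_rt))
        holds <- simulate_holds(p, config)
        list(pmsa = pmsa(rap_m, map_m, co_m, p$c_const),
             fit = vr_curve(holds, flow = config$flow), base = base)
      }, pms_circulatory_collapse = function(e) NULL,
         pms_insufficient_data = function(e) NULL,
         pms_nonphysiologic_fit = function(e) NULL)
      if (!is.null(res)) break
      redraws <- redraws + 1L
    }
    if (is.null(res))
      pms_stop("could not draw an analyzable virtual patient in 25 attempts",
               "pms_invalid_argument")
    base <- res$base
    rows[[i]] <- data.frame(
      patient_id = sprintf("VP%02d", i),
      pmsa = res$pmsa, pms_insp = res$fit$pms_insp,
      vasopressor = rbinom(1, 1, 8 / 18) == 1,
      age_y = p$age_y, height_cm = p$height_cm, weight_kg = p$weight_kg,
      pms_true = p$pms_true, rvr = p$rvr, svr = p$svr, c_const = p$c_const,
      bsa = p$bsa, rap0 = base$rap, co0 = base$co,
      transmission = p$transmission)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "redraws") <- redraws
  class(out) <- c("pms_cohort", "data.frame")
  out
}
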