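#' Fit a venous return curve and extrapolate to zero flow
#'
#' Fits the Guytonian venous return line, flow = intercept + slope * RAP,
#' to inspiratory-hold measurements by ordinary least squares, and
#' extrapolates to the zero-flow x-intercept. That intercept is the
#' inspiratory-hold estimate of mean systemic filling pressure (Pms-Insp):
#' the right atrial pressure at which venous return — and hence, in steady
#' state, cardiac output — would cease.
#'
#' The flow axis is cardiac index by default (as venous return curves are
#' conventionally plotted); fitting cardiac output instead rescales slope
#' and intercept by body surface area but leaves the x-intercept, and so
#' Pms-Insp, unchanged.
#'
#' @param holds Data frame of hold measurements with columns `rap` (mmHg)
#'   and the flow column (`ci`, L/min/m2, or `co`, L/min); typically from
#'   [extract_hold_values()], [read_holds_csv()] or [simulate_holds()].
#' @param flow Which column carries the flow axis: `"ci"` (default) or
#'   `"co"`.
#' @return An object of class `vr_curve`: a list with `coefficients`
#'   (intercept, slope), `pms_insp` (mmHg), `r_squared`, `residual_sd`,
#'   `n`, `flow`, the underlying `lm` fit and the data. Standard methods
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals` and
#'   `plot` apply.
#' @section Errors: fewer than 3 points raises `pms_insufficient_data`;
#'   all-identical RAP values raise `pms_degenerate_design`; a
#'   non-negative slope (no zero-flow intercept on the physiologic side)
#'   raises `pms_nonphysiologic_fit`.
#' @examples
#' h <- data.frame(rap = c(5, 10, 15), ci = c(3, 2, 1))
#' fit <- vr_curve(h)
#' fit$pms_insp  # 20 mmHg
#' @export
vr_curve <- function(holds, flow = c("ci", "co")) {
  flow <- match.arg(flow)
  if (!is.data.frame(holds) || !all(c("rap", flow) %in% names(holds)))
    pms_stop(paste0("holds needs columns rap and ", flow), "pms_data_format")
  d <- data.frame(rap = as.numeric(holds$rap), y = as.numeric(holds[[flow]]))
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3)
    pms_stop("venous return curve needs at least 3 hold measurements",
             "pms_insufficient_data")
  if (length(unique(d$rap)) == 1L)
    pms_stop("all RAP values identical: regression design is degenerate",
             "pms_degenerate_design")
  fit <- lm(y ~ rap, data = d)
  b <- unname(coef(fit))
  if (b[2] >= 0)
    pms_stop(sprintf("fitted slope %.4g >= 0: flow does not fall with RAP, no physiologic zero-flow intercept", b[2]),
             "pms_nonphysiologic_fit")
  # perfect collinearity is a legitimate case here (noiseless simulation),
  # so the "essentially perfect fit" warning is suppressed
  s <- suppressWarnings(summary(fit))
  structure(list(
    coefficients = c(intercept = b[1], slope = b[2]),
    pms_insp = -b[1] / b[2],
    r_squared = s$r.squared,
    residual_sd = s$sigma,
    n = nrow(d),
    flow = flow,
    fit = fit,
    data = d
  ), class = "vr_curve")
}

#' @export
print.vr_curve <- function(x, digits = 3, ...) {
  cat("Venous return curve (", x$n, " inspiratory holds, flow axis: ",
      toupper(x$flow), ")\n", sep = "")
  cat(sprintf("  slope      %8.*f %s per mmHg\n", digits, x$coefficients[["slope"]],
              if (x$flow == "ci") "L/min/m2" else "L/min"))
  cat(sprintf("  intercept  %8.*f %s\n", digits, x$coefficients[["intercept"]],
              if (x$flow == "ci") "L/min/m2" else "L/min"))
  cat(sprintf("  Pms-Insp   %8.2f mmHg (zero-flow intercept)\n", x$pms_insp))
  cat(sprintf("  R-squared  %8.*f, residual SD %.*g\n", digits, x$r_squared,
              digits, x$residual_sd))
  invisible(x)
}

#' @export
summary.vr_curve <- function(object, ...) {
  out <- list(curve = object, lm_summary = summary(object$fit))
  class(out) <- "summary.vr_curve"
  out
}

#' @export
print.summary.vr_curve <- function(x, ...) {
  print(x$curve)
  cat("\nUnderlying least-squares fit:\n")
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.vr_curve <- function(object, ...) object$coefficients

#' @export
fitted.vr_curve <- function(object, ...) fitted(object$fit)

#' @export
residuals.vr_curve <- function(object, ...) residuals(object$fit)

#' Predict flow at given right atrial pressures
#' @param object A `vr_curve` fit.
#' @param rap Right atrial pressures (mmHg) at which to evaluate the line;
#'   defaults to the fitted points.
#' @param ... Unused.
#' @return Predicted flow on the fitted flow axis.
#' @export
predict.vr_curve <- function(object, rap = NULL, ...) {
  if (is.null(rap)) return(fitted(object$fit))
  unname(object$coefficients[1] + object$coefficients[2] * rap)
}

#' Plot a venous return curve
#' @param x A `vr_curve` fit.
#' @param ... Passed to `plot.default`.
#' @export
plot.vr_curve <- function(x, ...) {
  xr <- range(c(x$data$rap, x$pms_insp))
  plot(x$data$rap, x$data$y, xlim = xr + c(-0.5, 0.5),
       ylim = c(0, max(x$data$y) * 1.05),
       xlab = "RAP (mmHg)",
       ylab = if (x$flow == "ci") "CI (L/min/m2)" else "CO (L/min)",
       main = "Venous return curve", ...)
  abline(x$coefficients[1], x$coefficients[2], lty = 2)
  points(x$pms_insp, 0, pch = 4, cex = 1.4)
  legend("topright", bty = "n",
         legend = sprintf("Pms-Insp = %.2f mmHg", x$pms_insp))
  invisible(x)
}

#' Extract per-hold plateau values from a monitor stream
#'
#' Summarizes RAP and flow over the stabilized tail of each tagged
#' inspiratory-hold window (mean of the final `tail_s` seconds, when the
#' circulation has settled to its hold operating point).
#'
#' @param stream Monitor stream data frame (`time`, `rap`, `map`, `co`).
#' @param windows Data frame of hold windows: `start`, `end` (s), and
#'   `pplateau` (cm H2O).
#' @param tail_s Length of the averaged tail, seconds (default 3).
#' @param bsa Body surface area in m2, used to derive cardiac index from
#'   the CO channel; if `NULL` the `ci` column is left `NA`.
#' @return Data frame with one row per hold: `pplateau`, `rap`, `co`,
#'   `ci`, `duration`.
#' @section Errors: windows shorter than 12 s raise
#'   `pms_protocol_violation`; missing channels raise `pms_data_format`.
#' @export
extract_hold_values <- function(stream, windows, tail_s = 3, bsa = NULL) {
  need <- c("time", "rap", "map", "co")
  if (!is.data.frame(stream) || !all(need %in% names(stream)))
    pms_stop("stream needs columns time, rap, map, co", "pms_data_format")
  if (!all(c("start", "end", "pplateau") %in% names(windows)))
    pms_stop("windows need start, end, pplateau columns", "pms_data_format")
  dur <- windows$end - windows$start
  if (any(dur < 12))
    pms_stop("inspiratory hold shorter than 12 s", "pms_protocol_violation")
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    sel <- stream$time > windows$end[i] - tail_s & stream$time <= windows$end[i]
    if (!any(sel))
      pms_stop("no stream samples inside a hold tail window", "pms_data_format")
    co <- mean(stream$co[sel])
    data.frame(pplateau = windows$pplateau[i],
               rap = mean(stream$rap[sel]),
               co = co,
               ci = if (is.null(bsa)) NA_real_ else co / bsa,
               duration = dur[i])
  })
  do.call(rbind, rows)
}

#' Check inspiratory-hold measurements against the study protocol
#'
#' Advisory screen of a hold table against the stepwise protocol: plateau
#' pressures 5-10-15-20-25-30 cm H2O, each hold at least 12 s, tidal
#' volumes strictly below 1000 mL, and (when hold start times are given)
#' 2-minute intervals between steps. Findings are returned, never raised;
#' the data are not modified.
#'
#' @param holds Hold table with columns `pplateau` and optionally
#'   `duration` (s).
#' @param schedule Expected plateau schedule in cm H2O.
#' @param min_hold_s Minimum hold duration, seconds.
#' @param tidal_volume_ml Optional tidal volume(s) to screen (< 1000 mL).
#' @param start_times Optional hold start times (s) to check spacing.
#' @param interval_s,interval_tol_s Expected spacing between consecutive
#'   holds and its tolerance, seconds.
#' @return Data frame of findings (`check`, `detail`); zero rows when the
#'   protocol was followed.
#' @export
validate_protocol <- function(holds, schedule = c(5, 10, 15, 20, 25, 30),
                              min_hold_s = 12, tidal_volume_ml = NULL,
                              start_times = NULL, interval_s = 120,
                              interval_tol_s = 30) {
  findings <- list()
  add <- function(check, detail)
    findings[[length(findings) + 1L]] <<- data.frame(check = check, detail = detail)
  miss <- setdiff(schedule, holds$pplateau)
  if (length(miss))
    add("missing_pressure_step",
        paste("no hold at plateau", paste(miss, collapse = ", "), "cm H2O"))
  extra <- setdiff(holds$pplateau, schedule)
  if (length(extra))
    add("off_schedule_step",
        paste("hold at unscheduled plateau", paste(extra, collapse = ", "), "cm H2O"))
  if ("duration" %in% names(holds)) {
    short <- holds$pplateau[holds$duration < min_hold_s]
    if (length(short))
      add("short_hold", paste("hold <", min_hold_s, "s at plateau",
                              paste(short, collapse = ", ")))
  }
  if (!is.null(tidal_volume_ml) && any(tidal_volume_ml >= 1000))
    add("tidal_volume", "tidal volume >= 1000 mL/breath")
  if (!is.null(start_times) && length(start_times) > 1) {
    gaps <- diff(sort(start_times))
    if (any(abs(gaps - interval_s) > interval_tol_s))
      add("interval", sprintf("inter-hold interval outside %g +/- %g s",
                              interval_s, interval_tol_s))
  }
  if (!length(findings))
    return(data.frame(check = character(), detail = character()))
  do.call(rbind, findings)
}
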