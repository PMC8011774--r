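#' Limits of agreement from bias and precision
#'
#' Bland-Altman 95% limits of agreement, `bias +/- 1.96 * SD` of the
#' paired differences.
#'
#' @param bias Mean of the paired differences, mmHg.
#' @param sd_diff Standard deviation of the paired differences (the
#'   precision), mmHg.
#' @return Named numeric `c(lower, upper)`.
#' @examples
#' loa_limits(-0.502, 1.90)
#' @export
loa_limits <- function(bias, sd_diff) {
  if (!is.numeric(bias) || !is.numeric(sd_diff) || any(sd_diff < 0))
    pms_stop("bias must be numeric and sd_diff a nonnegative numeric",
             "pms_invalid_argument")
  c(lower = bias - 1.96 * sd_diff, upper = bias + 1.96 * sd_diff)
}

#' Bland-Altman analysis of two Pms estimates
#'
#' Per-subject differences are taken as `pmsa - pms_insp` (test minus
#' reference), so a negative bias means the analogue reads below the
#' inspiratory-hold estimate. Reports bias (mean difference), precision
#' (SD of differences), 95% limits of agreement, a one-sample t test of
#' the bias against zero, proportional bias (OLS slope of difference on
#' pairwise mean with its p-value), and an advisory Kolmogorov-Smirnov
#' check of the differences against a moment-fitted normal.
#'
#' @param pmsa Analogue estimates, mmHg (test method).
#' @param pms_insp Inspiratory-hold estimates, mmHg (reference method).
#' @return Object of class `bland_altman`: list with `n`, `bias`,
#'   `sd_diff`, `loa` (lower, upper), `bias_p`, `prop_bias` (slope,
#'   p, intercept), `normality` (statistic, p), and the raw `diffs` and
#'   pairwise `means`.
#' @export
bland_altman <- function(pmsa, pms_insp) {
  if (length(pmsa) != length(pms_insp))
    pms_stop("pmsa and pms_insp must be the same length", "pms_invalid_argument")
  if (any(!is.finite(pmsa)) || any(!is.finite(pms_insp)))
    pms_stop("both pressure vectors must be finite", "pms_invalid_argument")
  n <- length(pmsa)
  if (n < 2)
    pms_stop("Bland-Altman needs at least 2 pairs", "pms_insufficient_data")
  diffs <- pmsa - pms_insp
  means <- (pmsa + pms_insp) / 2
  bias <- mean(diffs)
  sd_diff <- sd(diffs)
  bias_p <- if (sd_diff > 0) t.test(diffs)$p.value else NA_real_
  prop <- list(slope = NA_real_, p = NA_real_, intercept = NA_real_)
  if (n >= 3 && sd(means) > 0 && sd_diff > 0) {
    fit <- summary(lm(diffs ~ means))$coefficients
    if (nrow(fit) == 2)
      prop <- list(slope = fit[2, 1], p = fit[2, 4], intercept = fit[1, 1])
  }
  normality <- list(statistic = NA_real_, p = NA_real_)
  if (sd_diff > 0) {
    ks <- suppressWarnings(ks.test(diffs, "pnorm", bias, sd_diff))
    normality <- list(statistic = unname(ks$statistic), p = ks$p.value)
  }
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa = loa_limits(bias, sd_diff), bias_p = bias_p,
                 prop_bias = prop, normality = normality,
                 sign_convention = "pmsa - pms_insp",
                 diffs = diffs, means = means),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Bland-Altman agreement (differences = Pmsa - Pms-Insp), n =", x$n, "\n")
  cat(sprintf("  bias       %8.3f mmHg (p = %s)\n", x$bias, format.pval(x$bias_p, digits = 3)))
  cat(sprintf("  precision  %8.2f mmHg (SD of differences)\n", x$sd_diff))
  cat(sprintf("  95%% LOA    %8.2f to %.2f mmHg\n", x$loa[1], x$loa[2]))
  if (is.finite(x$prop_bias$slope))
    cat(sprintf("  proportional bias: B = %.3f (p = %s)\n",
                x$prop_bias$slope, format.pval(x$prop_bias$p, digits = 3)))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#' @param x A `bland_altman` object.
#' @param ... Passed to `plot.default`.
#' @export
plot.bland_altman <- function(x, ...) {
  plot(x$means, x$diffs, xlab = "Mean of methods (mmHg)",
       ylab = "Pmsa - Pms-Insp (mmHg)", main = "Bland-Altman", ...)
  abline(h = x$bias, lty = 2)
  abline(h = x$loa, lty = 3)
  invisible(x)
}

#' Two-way mixed-model intraclass correlation, absolute agreement
#'
#' ICC for absolute agreement under the two-way mixed model (subjects
#' random, raters/methods fixed), computed from the two-way ANOVA mean
#' squares. Both the single-rater form ICC(A,1) and the average-measures
#' form ICC(A,k) are returned, with 95% confidence bounds from the
#' F-distribution (McGraw-Wong; average-measures bounds by
#' Spearman-Brown), and the p-value of the F test of ICC = 0
#' (`F = MS_rows / MS_error` on (n-1, (n-1)(k-1)) df).
#'
#' @param ratings Either an n x k numeric matrix (subjects in rows,
#'   methods in columns) or the first method's vector, with `y` the
#'   second.
#' @param y Optional second rating vector.
#' @param conf_level Confidence level for the bounds (default 0.95).
#' @return Object of class `icc_agreement`: list with `icc_single`,
#'   `ci_single`, `icc_avg`, `ci_avg`, `f`, `df1`, `df2`, `p`, the mean
#'   squares `ms`, and `n`, `k`.
#' @section Errors: zero between-subject variance leaves the ICC
#'   undefined and raises `pms_undefined_icc`.
#' @export
icc_agreement <- function(ratings, y = NULL, conf_level = 0.95) {
  M <- if (!is.null(y)) cbind(as.numeric(ratings), as.numeric(y)) else as.matrix(ratings)
  if (any(!is.finite(M)))
    pms_stop("ratings must be finite", "pms_invalid_argument")
  n <- nrow(M); k <- ncol(M)
  if (n < 3 || k < 2)
    pms_stop("ICC needs at least 3 subjects and 2 ratings", "pms_insufficient_data")
  gm <- mean(M)
  MSR <- k * sum((rowMeans(M) - gm)^2) / (n - 1)
  MSC <- n * sum((colMeans(M) - gm)^2) / (k - 1)
  SSE <- sum((M - gm)^2) - (n - 1) * MSR - (k - 1) * MSC
  MSE <- max(SSE, 0) / ((n - 1) * (k - 1))
  if (MSR <= 0)
    pms_stop("zero between-subject variance: ICC undefined", "pms_undefined_icc")
  alpha <- 1 - conf_level
  sb <- function(r) r * k / (1 + (k - 1) * r)  # Spearman-Brown step-up
  if (MSE == 0 && MSC == 0) {
    # identical columns: perfect absolute agreement
    icc1 <- 1; icck <- 1
    ci1 <- c(1, 1); cik <- c(1, 1)
    f <- Inf; p <- 0
  } else {
    icc1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    icck <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
    Fj <- MSC / MSE
    vn <- (k - 1) * (n - 1) * (k * icc1 * Fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
    vd <- (n - 1) * k^2 * icc1^2 * Fj^2 + (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    FL <- qf(1 - alpha / 2, n - 1, v)
    FU <- qf(1 - alpha / 2, v, n - 1)
    ci1 <- c(n * (MSR - FL * MSE) / (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR),
             n * (FU * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * FU * MSR))
    cik <- sb(ci1)
    f <- MSR / MSE
    p <- pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  structure(list(icc_single = icc1, ci_single = ci1,
                 icc_avg = icck, ci_avg = cik,
                 f = f, df1 = n - 1, df2 = (n - 1) * (k - 1), p = p,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE),
                 n = n, k = k, conf_level = conf_level),
            class = "icc_agreement")
}

#' @export
print.icc_agreement <- function(x, ...) {
  cl <- round(100 * x$conf_level)
  cat("Intraclass correlation, two-way mixed model, absolute agreement\n")
  cat(sprintf("  ICC(A,1)  %.2f (%d%% CI %.2f-%.2f)\n", x$icc_single, cl,
              x$ci_single[1], x$ci_single[2]))
  cat(sprintf("  ICC(A,%d)  %.2f (%d%% CI %.2f-%.2f)  [average measures]\n",
              x$k, x$icc_avg, cl, x$ci_avg[1], x$ci_avg[2]))
  cat(sprintf("  F(%d,%d) = %.3g, p = %s\n", x$df1, x$df2, x$f,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

# exact null distribution of a sum over selected (doubled, integer) ranks,
# by generating-function convolution; handles mid-ranks from ties
.signed_rank_p <- function(d) {
  r2 <- round(2 * rank(abs(d)))
  V2 <- sum(r2[d > 0])
  dp <- c(1, numeric(sum(r2)))
  for (ri in r2) {
    shifted <- c(numeric(ri), dp[seq_len(length(dp) - ri)])
    dp <- dp + shifted
  }
  dp <- dp / 2^length(d)
  lo <- sum(dp[seq_len(V2 + 1L)])            # P(W <= v)
  hi <- sum(dp[(V2 + 1L):length(dp)])        # P(W >= v)
  min(1, 2 * min(lo, hi))
}

# exact null distribution of the rank-sum over group-label permutations
# (doubled mid-ranks); dp over (number chosen, doubled rank sum)
.rank_sum_p <- function(a, b) {
  m <- length(a); N <- m + length(b)
  r2 <- round(2 * rank(c(a, b)))
  S <- sum(r2)
  dp <- matrix(0, nrow = m + 1L, ncol = S + 1L)
  dp[1L, 1L] <- 1
  for (ri in r2) {
    for (j in m:1) {
      row <- dp[j, ]
      if (any(row != 0))
        dp[j + 1L, (ri + 1L):(S + 1L)] <- dp[j + 1L, (ri + 1L):(S + 1L)] +
          row[seq_len(S + 1L - ri)]
    }
  }
  pm <- dp[m + 1L, ] / choose(N, m)
  W2 <- sum(r2[seq_len(m)])
  lo <- sum(pm[seq_len(W2 + 1L)])
  hi <- sum(pm[(W2 + 1L):length(pm)])
  min(1, 2 * min(lo, hi))
}

#' Paired rank test of two Pms estimates (Wilcoxon signed rank)
#'
#' Two-sided signed-rank test of the per-subject differences. Zero
#' differences are dropped (and counted); ties among the absolute
#' differences take mid-ranks. The p-value is exact for `n <= exact_limit`
#' retained differences — via `stats::wilcox.test` when there are no ties,
#' and via an exact convolution of the tied mid-rank distribution
#' otherwise — and a tie-corrected normal approximation with continuity
#' correction above that.
#'
#' @param x First method's values, or the differences themselves if `y`
#'   is `NULL`.
#' @param y Optional second method's values.
#' @param exact_limit Largest n for which the exact distribution is used
#'   (default 25).
#' @return List with `p.value`, `statistic` (V, sum of positive ranks),
#'   `n_used`, `n_zero`, `method`, and `all_zero` flag (`p = 1` by
#'   convention when every difference is zero).
#' @export
paired_rank_test <- function(x, y = NULL, exact_limit = 25) {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 1 || any(!is.finite(d)))
    pms_stop("need at least one finite difference", "pms_insufficient_data")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p.value = 1, statistic = c(V = NA_real_), n_used = 0L,
                n_zero = n_zero, method = "all differences zero", all_zero = TRUE))
  V <- sum(rank(abs(d))[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= exact_limit) {
    if (!ties) {
      p <- suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
      method <- "exact signed rank"
    } else {
      p <- .signed_rank_p(d)
      method <- "exact signed rank, mid-rank ties"
    }
  } else {
    p <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(p.value = p, statistic = c(V = V), n_used = n, n_zero = n_zero,
       method = method, all_zero = FALSE)
}

#' Unpaired rank test between two groups (Mann-Whitney U)
#'
#' Two-sided rank-sum test of a location shift between two independent
#' groups. Exact for small samples — via `stats::wilcox.test` without
#' ties, via an exact permutation convolution of mid-ranks with ties —
#' and a tie-corrected normal approximation for larger samples.
#'
#' @param a,b Numeric vectors for the two groups.
#' @param exact_limit Largest per-group n for the exact distribution.
#' @return List with `p.value`, `statistic` (U), `n` and `method`.
#' @export
unpaired_rank_test <- function(a, b, exact_limit = 25) {
  if (length(a) < 1 || length(b) < 1 || any(!is.finite(c(a, b))))
    pms_stop("both groups need at least one finite value", "pms_insufficient_data")
  m <- length(a); n <- length(b)
  U <- sum(rank(c(a, b))[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (m <= exact_limit && n <= exact_limit) {
    if (!ties) {
      p <- suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value)
      method <- "exact rank sum"
    } else {
      p <- .rank_sum_p(a, b)
      method <- "exact rank sum, mid-rank ties"
    }
  } else {
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    method <- "normal approximation"
  }
  list(p.value = p, statistic = c(U = U), n = c(m, n), method = method)
}

#' Conversion coefficient between the two Pms estimates
#'
#' Per-subject ratio `pms_insp / pmsa`; its mean is the coefficient that
#' converts an analogue value into an inspiratory-hold value, and the
#' reciprocal of the mean (rounded to 2 decimals) is the factor relating
#' Pmsa to Pms-Insp.
#'
#' @param pmsa Analogue estimates, mmHg; must all be > 0.
#' @param pms_insp Inspiratory-hold estimates, mmHg.
#' @return List with `conv_mean`, `conv_sd`, `conv_factor`, `ratios`.
#' @export
conversion_coefficient <- function(pmsa, pms_insp) {
  if (length(pmsa) != length(pms_insp) || any(!is.finite(c(pmsa, pms_insp))))
    pms_stop("need equal-length finite vectors", "pms_invalid_argument")
  if (any(pmsa <= 0))
    pms_stop("conversion ratio undefined for non-positive Pmsa", "pms_invalid_ratio")
  ratios <- pms_insp / pmsa
  m <- mean(ratios)
  list(conv_mean = m,
       conv_sd = if (length(ratios) > 1) sd(ratios) else NA_real_,
       conv_factor = round(1 / m, 2),
       ratios = ratios)
}

#' Coefficient of variance
#'
#' `100 * SD / mean` in percent. Two definitions are supported:
#' `"sd_over_mean"` uses the SD and mean of `values`;
#' `"diff_sd_over_mean"` uses the SD of the paired differences `diffs`
#' over the mean of all paired measurements `values` (the definition used
#' in the agreement report).
#'
#' @param values Numeric vector whose mean forms the denominator (and,
#'   under the first definition, whose SD forms the numerator).
#' @param definition One of `"sd_over_mean"`, `"diff_sd_over_mean"`.
#' @param diffs Paired differences (required for the second definition).
#' @return COV in percent.
#' @export
cov_percent <- function(values, definition = c("sd_over_mean", "diff_sd_over_mean"),
                        diffs = NULL) {
  definition <- match.arg(definition)
  m <- mean(values)
  if (!is.finite(m) || m == 0)
    pms_stop("coefficient of variance undefined for zero mean", "pms_undefined_value")
  s <- switch(definition,
              sd_over_mean = sd(values),
              diff_sd_over_mean = {
                if (is.null(diffs))
                  pms_stop("diffs required for diff_sd_over_mean", "pms_invalid_argument")
                sd(diffs)
              })
  100 * s / m
}

#' Post-hoc power of the ICC significance test
#'
#' Power of the F-based test that the intraclass correlation exceeds a
#' null value, under the Walter-Eliasziw-Donner construction: with n
#' subjects and k ratings each, `MS_between / MS_within` is distributed as
#' `C(rho) * F(n-1, n(k-1))` where `C(rho) = 1 + k*rho/(1-rho)`, so the
#' power at an alternative ICC is an F-tail probability of the rescaled
#' critical value.
#'
#' @param n Number of subjects (>= 3).
#' @param k Ratings per subject (>= 2).
#' @param icc_alt Alternative-hypothesis ICC, in `[icc_null, 1)`.
#' @param icc_null Null-hypothesis ICC, in `[0, 1)` (default 0).
#' @param alpha Significance level (default 0.05).
#' @param tails 1 or 2 (default 2).
#' @return Power in `[0, 1]`; equals `alpha` when `icc_alt == icc_null`.
#' @examples
#' icc_power(n = 18, k = 2, icc_alt = 0.89)  # > 0.99
#' @export
icc_power <- function(n, k, icc_alt, icc_null = 0, alpha = 0.05, tails = 2) {
  ok <- is.numeric(n) && n >= 3 && is.numeric(k) && k >= 2 &&
    is.numeric(icc_alt) && is.numeric(icc_null) &&
    icc_null >= 0 && icc_null <= icc_alt && icc_alt < 1 &&
    alpha > 0 && alpha < 1 && tails %in% c(1, 2)
  if (!ok)
    pms_stop("invalid icc_power parameters: need n>=3, k>=2, 0<=icc_null<=icc_alt<1, 0<alpha<1, tails 1 or 2",
             "pms_invalid_argument")
  v1 <- n - 1
  v2 <- n * (k - 1)
  C0 <- 1 + k * icc_null / (1 - icc_null)
  C1 <- 1 + k * icc_alt / (1 - icc_alt)
  a <- if (tails == 2) alpha / 2 else alpha
  pow <- pf(C0 / C1 * qf(1 - a, v1, v2), v1, v2, lower.tail = FALSE)
  if (tails == 2) pow <- pow + pf(C0 / C1 * qf(a, v1, v2), v1, v2)
  unname(pow)
}

#' Thermodilution triplet calibration check
#'
#' A calibration triplet of thermodilution cardiac-output measurements is
#' accepted only if no measurement deviates from the triplet mean by more
#' than 10%.
#'
#' @param co Exactly three positive CO values, L/min.
#' @return List with `accepted` (logical), `mean`, `deviations`
#'   (fractional deviation of each value from the mean) and
#'   `max_deviation`.
#' @examples
#' triplet_qc(c(5.0, 5.2, 4.9))$accepted  # TRUE
#' triplet_qc(c(5.0, 5.0, 6.0))$accepted  # FALSE
#' @export
triplet_qc <- function(co) {
  if (!is.numeric(co) || length(co) != 3 || any(!is.finite(co)) || any(co <= 0))
    pms_stop("triplet_qc needs exactly 3 positive CO values", "pms_invalid_argument")
  m <- mean(co)
  dev <- abs(co - m) / m
  list(accepted = all(dev <= 0.10), mean = m,
       deviations = dev, max_deviation = max(dev))
}

# one stratum of the agreement report
.analyze_stratum <- function(pmsa, pms_insp, cov_definition, conf_level, findings, label) {
  n <- length(pmsa)
  out <- list(n = n,
              median_pmsa = median(pmsa), iqr_pmsa = unname(quantile(pmsa, c(0.25, 0.75))),
              median_pms_insp = median(pms_insp),
              iqr_pms_insp = unname(quantile(pms_insp, c(0.25, 0.75))))
  out$paired_rank <- paired_rank_test(pmsa, pms_insp)
  if (n >= 2) {
    out$bland_altman <- bland_altman(pmsa, pms_insp)
    out$cov_percent <- tryCatch(
      cov_percent(c(pmsa, pms_insp), definition = cov_definition,
                  diffs = pmsa - pms_insp),
      pmsagree_error = function(e) NA_real_)
  } else {
    findings$add(label, "descriptive fields only: agreement statistics need n >= 2")
  }
  if (n >= 3) {
    out$icc <- tryCatch(icc_agreement(pmsa, pms_insp, conf_level = conf_level),
                        pms_undefined_icc = function(e) {
                          findings$add(label, conditionMessage(e)); NULL
                        })
  } else if (n >= 2) {
    findings$add(label, "ICC needs n >= 3")
  }
  out$conversion <- if (all(pmsa > 0)) conversion_coefficient(pmsa, pms_insp) else {
    findings$add(label, "conversion coefficient undefined (non-positive Pmsa)")
    NULL
  }
  out
}

#' Run the full method-agreement study
#'
#' Reproduces the complete statistical comparison of the analogue and
#' inspiratory-hold Pms estimates on a paired cohort: medians with IQR and
#' a paired signed-rank test, Bland-Altman bias / precision / limits of
#' agreement with proportional-bias regression, two-way mixed
#' absolute-agreement ICC with 95% CI, coefficient of variance and the
#' conversion coefficient — overall and within the vasopressor and
#' no-vasopressor strata, plus unpaired rank tests of each estimate
#' between the strata.
#'
#' @param pairs Data frame with columns `pmsa`, `pms_insp` (mmHg) and
#'   optionally `vasopressor` (logical or 0/1) and `patient_id`;
#'   e.g. from [read_pairs_csv()] or [simulate_cohort()].
#' @param cov_definition Definition passed to [cov_percent()]; the
#'   default relates the SD of the paired differences to the mean of all
#'   paired measurements.
#' @param conf_level Confidence level for ICC bounds.
#' @return Object of class `pms_agreement`: list of per-stratum reports
#'   (`overall`, `vasopressor`, `no_vasopressor`), `between` (unpaired
#'   rank tests between strata), the sign convention, the COV definition
#'   used, and advisory `findings`.
#' @export
run_study <- function(pairs, cov_definition = "diff_sd_over_mean",
                      conf_level = 0.95) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0)
    pms_stop("pairs must be a nonempty data frame", "pms_insufficient_data")
  if (!all(c("pmsa", "pms_insp") %in% names(pairs)))
    pms_stop("pairs needs columns pmsa and pms_insp", "pms_data_format")
  if (any(!is.finite(pairs$pmsa)) || any(!is.finite(pairs$pms_insp)))
    pms_stop("non-finite Pms values in pairs", "pms_invalid_argument")
  if ("patient_id" %in% names(pairs) && anyDuplicated(pairs$patient_id))
    pms_stop("one record per patient required (duplicate patient_id)",
             "pms_data_format")
  logged <- list()
  findings <- list(add = function(where, what)
    logged[[length(logged) + 1L]] <<- data.frame(stratum = where, finding = what))
  strata <- list(overall = rep(TRUE, nrow(pairs)))
  if ("vasopressor" %in% names(pairs)) {
    vp <- as.logical(pairs$vasopressor)
    strata$vasopressor <- vp
    strata$no_vasopressor <- !vp
  }
  reports <- list()
  for (nm in names(strata)) {
    sel <- strata[[nm]]
    if (!any(sel)) {
      findings$add(nm, "empty stratum skipped")
      reports[[nm]] <- NULL
      next
    }
    reports[[nm]] <- .analyze_stratum(pairs$pmsa[sel], pairs$pms_insp[sel],
                                      cov_definition, conf_level, findings, nm)
  }
  between <- NULL
  if (!is.null(strata$vasopressor) && any(strata$vasopressor) && any(strata$no_vasopressor)) {
    between <- list(
      pmsa = unpaired_rank_test(pairs$pmsa[strata$vasopressor],
                                pairs$pmsa[strata$no_vasopressor]),
      pms_insp = unpaired_rank_test(pairs$pms_insp[strata$vasopressor],
                                    pairs$pms_insp[strata$no_vasopressor]))
  }
  structure(list(strata = reports, between = between,
                 sign_convention = "pmsa - pms_insp",
                 cov_definition = cov_definition,
                 findings = if (length(logged)) do.call(rbind, logged) else NULL,
                 n = nrow(pairs)),
            class = "pms_agreement")
}

# reporting rounding: pressures/LOA 2 dp, bias 3 dp, ICC 2 dp
.fmt_stratum <- function(s, name) {
  line <- function(...) cat(sprintf(...), "\n", sep = "")
  cat("--- ", name, " (n = ", s$n, ") ---\n", sep = "")
  line("  Pmsa      median %.2f mmHg (IQR %.2f-%.2f)", s$median_pmsa,
       s$iqr_pmsa[1], s$iqr_pmsa[2])
  line("  Pms-Insp  median %.2f mmHg (IQR %.2f-%.2f)", s$median_pms_insp,
       s$iqr_pms_insp[1], s$iqr_pms_insp[2])
  line("  paired signed-rank p = %s", format.pval(s$paired_rank$p.value, digits = 2))
  if (!is.null(s$bland_altman)) {
    ba <- s$bland_altman
    line("  bias %.3f +/- %.2f mmHg (p = %s), LOA %.2f to %.2f",
         ba$bias, ba$sd_diff, format.pval(ba$bias_p, digits = 2),
         ba$loa[1], ba$loa[2])
    if (is.finite(ba$prop_bias$slope))
      line("  proportional bias B = %.3f (p = %s)", ba$prop_bias$slope,
           format.pval(ba$prop_bias$p, digits = 2))
  }
  if (!is.null(s$icc))
    line("  ICC (average measures) %.2f (95%% CI %.2f-%.2f, p = %s)",
         s$icc$icc_avg, s$icc$ci_avg[1], s$icc$ci_avg[2],
         format.pval(s$icc$p, digits = 2))
  if (!is.null(s$cov_percent) && is.finite(s$cov_percent %||% NA))
    line("  COV %.0f%%", s$cov_percent)
  if (!is.null(s$conversion))
    line("  conversion coefficient %.2f +/- %.2f (factor %.2f)",
         s$conversion$conv_mean, s$conversion$conv_sd %||% NA_real_,
         s$conversion$conv_factor)
}

#' @export
print.pms_agreement <- function(x, ...) {
  cat("Agreement of Pmsa (analogue) vs Pms-Insp (inspiratory hold)\n")
  cat("differences:", x$sign_convention, "| COV definition:", x$cov_definition, "\n\n")
  for (nm in names(x$strata)) if (!is.null(x$strata[[nm]])) .fmt_stratum(x$strata[[nm]], nm)
  if (!is.null(x$between)) {
    cat("--- between strata (vasopressor vs none) ---\n")
    cat(sprintf("  Pmsa     Mann-Whitney p = %s\n",
                format.pval(x$between$pmsa$p.value, digits = 2)))
    cat(sprintf("  Pms-Insp Mann-Whitney p = %s\n",
                format.pval(x$between$pms_insp$p.value, digits = 2)))
  }
  if (!is.null(x$findings)) {
    cat("findings:\n")
    for (i in seq_len(nrow(x$findings)))
      cat("  [", x$findings$stratum[i], "] ", x$findings$finding[i], "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.pms_agreement <- function(object, ...) print(object, ...)
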