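test_that("limits of agreement are bias +/- 1.96 SD", {
  l <- loa_limits(-0.502, 1.90)
  expect_equal(unname(l), c(-0.502 - 1.96 * 1.90, -0.502 + 1.96 * 1.90))
  expect_error(loa_limits(0, -1), class = "pms_invalid_argument")
})

test_that("Bland-Altman on identical pairs gives zero bias and collapsed limits", {
  ba <- bland_altman(c(10, 11, 12), c(10, 11, 12))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(unname(ba$loa), c(0, 0))
  expect_true(is.na(ba$bias_p))
  expect_error(bland_altman(10, 10), class = "pms_insufficient_data")
})

test_that("Bland-Altman matches a hand-computed mean/SD/OLS oracle on a 5-pair fixture", {
  x <- c(10.2, 12.5, 9.1, 14.0, 11.3)   # pmsa
  y <- c(11.0, 12.1, 10.4, 13.2, 12.0)  # pms_insp
  d <- x - y; m <- (x + y) / 2
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / 4))
  expect_equal(unname(ba$loa), mean(d) + c(-1.96, 1.96) * sd(d))
  expect_equal(ba$bias_p, t.test(d)$p.value)
  ne <- normal_equations_fit(m, d)
  expect_equal(ba$prop_bias$slope, ne[2], tolerance = 1e-10)
})

test_that("swapping the methods flips the bias sign and mirrors the LOA; ICC is unchanged", {
  set.seed(5)
  x <- rnorm(12, 12, 2); y <- x + rnorm(12, -0.5, 1)
  a <- bland_altman(x, y); b <- bland_altman(y, x)
  expect_equal(b$bias, -a$bias)
  expect_equal(b$sd_diff, a$sd_diff)
  expect_equal(unname(b$loa), -rev(unname(a$loa)))
  expect_equal(icc_agreement(y, x)$icc_avg, icc_agreement(x, y)$icc_avg)
})

test_that("ICC is 1 on duplicated columns and matches the ANOVA oracle on fixtures", {
  x <- c(16.6, 9.6, 10.6, 11.2, 10.1, 10.1)
  dup <- icc_agreement(x, x)
  expect_equal(dup$icc_single, 1)
  expect_equal(dup$icc_avg, 1)
  y <- c(17.3, 9.5, 10.8, 13.4, 10.5, 12.8)
  got <- icc_agreement(x, y)
  want <- aov_icc(cbind(x, y))
  expect_equal(got$icc_single, want$single, tolerance = 1e-12)
  expect_equal(got$icc_avg, want$avg, tolerance = 1e-12)
  expect_equal(unname(got$ms), unname(unlist(want$ms)), tolerance = 1e-12)
  # p from the F test of MSR/MSE on ((n-1), (n-1)(k-1)) df
  expect_equal(got$p, pf(want$ms$MSR / want$ms$MSE, 5, 5, lower.tail = FALSE))
  # frozen from the cross-checked reference implementation of ICC(A,1)/(A,k)
  expect_equal(got$icc_single, 0.8631817, tolerance = 1e-6)
  expect_equal(got$ci_single, c(0.2434722, 0.9800873), tolerance = 1e-6)
  expect_equal(got$icc_avg, 0.9265674, tolerance = 1e-6)
  expect_equal(got$ci_avg, c(0.3916005, 0.9899435), tolerance = 1e-6)
})

test_that("absolute-agreement ICC is invariant to a shared shift but not a one-column shift", {
  set.seed(9)
  x <- rnorm(10, 12, 2); y <- x + rnorm(10, 0, 0.8)
  base <- icc_agreement(x, y)$icc_single
  expect_equal(icc_agreement(x + 5, y + 5)$icc_single, base, tolerance = 1e-12)
  shifted <- icc_agreement(x + 5, y)$icc_single  # negative control
  expect_false(isTRUE(all.equal(shifted, base, tolerance = 1e-4)))
  expect_lt(shifted, base)
})

test_that("ICC is undefined without between-subject variance and needs 3 subjects", {
  expect_error(icc_agreement(c(5, 5, 5), c(5, 5, 5)), class = "pms_undefined_icc")
  expect_error(icc_agreement(c(1, 2), c(1, 2)), class = "pms_insufficient_data")
})

test_that("ICC estimator is consistent: truth inside its own 95% CI in most replicates", {
  # subjects ~ N(0, rho), errors ~ N(0, 1-rho): intraclass correlation rho
  rho <- 0.8; n <- 200; reps <- 500
  set.seed(101)
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    s <- rnorm(n, 0, sqrt(rho))
    M <- cbind(s + rnorm(n, 0, sqrt(1 - rho)), s + rnorm(n, 0, sqrt(1 - rho)))
    ci <- icc_agreement(M)$ci_single
    cover[r] <- ci[1] <= rho && rho <= ci[2]
  }
  expect_gte(mean(cover), 0.90)
})

test_that("paired signed-rank p is exact against full enumeration (with and without ties)", {
  set.seed(21)
  for (r in 1:6) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n, 0.3, 1), if (r <= 3) 3 else 0)  # rounding induces ties
    d <- d[d != 0]
    if (length(d) < 3) next
    got <- paired_rank_test(d)
    expect_equal(got$p.value, enum_signed_rank_p(d), tolerance = 1e-12,
                 info = paste("case", r))
  }
  # n = 5 no-tie fixture agrees with stats::wilcox.test exactly
  d5 <- c(1.3, -0.4, 2.2, 0.9, -1.8)
  expect_equal(paired_rank_test(d5)$p.value,
               wilcox.test(d5, exact = TRUE)$p.value)
  expect_equal(paired_rank_test(d5)$p.value, enum_signed_rank_p(d5))
})

test_that("signed-rank handles zeros, mirrored differences and the all-zero case", {
  all0 <- paired_rank_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(all0$p.value, 1)
  expect_true(all0$all_zero)
  expect_equal(all0$n_zero, 3L)
  # perfectly mirrored differences sit at the null center
  mir <- paired_rank_test(c(2, -2, 1, -1, 3, -3))
  expect_equal(unname(mir$statistic), sum(rank(abs(c(2, -2, 1, -1, 3, -3)))) / 2)
  expect_equal(mir$p.value, 1)
  # zeros are dropped, not ranked
  z <- paired_rank_test(c(0, 0, 1.5, -0.7, 2.1))
  expect_equal(z$n_used, 3L)
  expect_equal(z$n_zero, 2L)
})

test_that("rank-sum p is exact against enumeration and sees no shift in identical groups", {
  set.seed(33)
  for (r in 1:4) {
    a <- round(rnorm(sample(3:6, 1), 10, 2), if (r <= 2) 3 else 0)
    b <- round(rnorm(sample(3:6, 1), 11, 2), if (r <= 2) 3 else 0)
    expect_equal(unpaired_rank_test(a, b)$p.value, enum_rank_sum_p(a, b),
                 tolerance = 1e-12, info = paste("case", r))
  }
  a <- c(9.1, 10.2, 11.3, 12.4)
  expect_equal(unpaired_rank_test(a, a)$p.value, 1)
  # agreement with stats::wilcox.test in the untied exact regime
  b <- c(9.5, 10.9, 11.8, 13.1, 8.2)
  expect_equal(unpaired_rank_test(a, b)$p.value,
               wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("conversion coefficient matches hand-computed ratios", {
  eq <- conversion_coefficient(c(10, 12), c(10, 12))
  expect_equal(eq$conv_mean, 1)
  expect_equal(eq$conv_factor, 1)
  x <- c(10, 12, 9, 11); y <- c(10.8, 12.5, 9.9, 11.4)
  got <- conversion_coefficient(x, y)
  expect_equal(got$conv_mean, mean(y / x))
  expect_equal(got$conv_sd, sd(y / x))
  expect_equal(got$conv_factor, round(1 / mean(y / x), 2))
  expect_error(conversion_coefficient(c(10, 0), c(11, 11)),
               class = "pms_invalid_ratio")
})

test_that("coefficient of variance follows its definition and shifts change it", {
  expect_equal(cov_percent(c(10, 10, 10)), 0)
  expect_equal(cov_percent(c(8, 10, 12)), 20)
  v <- c(8, 10, 12)
  expect_false(isTRUE(all.equal(cov_percent(v + 10), cov_percent(v))))
  expect_equal(sd(v + 10), sd(v))  # SD itself is shift-invariant
  expect_equal(cov_percent(c(9, 10, 11), definition = "diff_sd_over_mean",
                           diffs = c(-1, 0, 1)), 100 * 1 / 10)
  expect_error(cov_percent(c(-1, 0, 1)), class = "pms_undefined_value")
})

test_that("ICC power equals alpha at the null and grows with n towards 1", {
  expect_equal(icc_power(18, 2, icc_alt = 0.3, icc_null = 0.3), 0.05, tolerance = 1e-10)
  ns <- c(5, 10, 20, 40, 80, 200)
  pw <- vapply(ns, function(n) icc_power(n, 2, 0.5), 0)
  expect_true(all(diff(pw) > 0))
  expect_gt(icc_power(2000, 2, 0.5), 0.999)
  expect_error(icc_power(18, 2, icc_alt = 1), class = "pms_invalid_argument")
  expect_error(icc_power(18, 2, icc_alt = 0.3, icc_null = 0.5),
               class = "pms_invalid_argument")
  expect_error(icc_power(2, 2, 0.5), class = "pms_invalid_argument")
})

test_that("thermodilution triplet QC applies the 10% outlier rule", {
  expect_true(triplet_qc(c(5.0, 5.0, 5.0))$accepted)
  # mean 5.333, 6.0 deviates 12.5%
  r <- triplet_qc(c(5.0, 5.0, 6.0))
  expect_false(r$accepted)
  expect_equal(r$max_deviation, (6 - mean(c(5, 5, 6))) / mean(c(5, 5, 6)))
  expect_true(triplet_qc(c(5.0, 5.2, 4.9))$accepted)
  expect_error(triplet_qc(c(5, 5)), class = "pms_invalid_argument")
  expect_error(triplet_qc(c(5, 5, -1)), class = "pms_invalid_argument")
})

test_that("run_study populates all report fields and stratifies by vasopressor", {
  set.seed(14)
  n <- 18
  pairs <- data.frame(patient_id = sprintf("p%02d", 1:n),
                      pmsa = rnorm(n, 12, 2))
  pairs$pms_insp <- pairs$pmsa + rnorm(n, 0.5, 1.2)
  pairs$vasopressor = rep(c(TRUE, FALSE), c(8, 10))
  rep <- run_study(pairs)
  ov <- rep$strata$overall
  expect_equal(ov$n, 18)
  expect_equal(ov$bland_altman$bias, mean(pairs$pmsa - pairs$pms_insp))
  expect_equal(unname(ov$bland_altman$loa),
               unname(loa_limits(ov$bland_altman$bias, ov$bland_altman$sd_diff)))
  expect_true(ov$bland_altman$loa[1] <= ov$bland_altman$bias)
  expect_true(ov$bland_altman$bias <= ov$bland_altman$loa[2])
  expect_equal(rep$strata$vasopressor$n, 8)
  expect_equal(rep$strata$no_vasopressor$n, 10)
  expect_s3_class(ov$icc, "icc_agreement")
  expect_true(is.finite(ov$cov_percent))
  expect_true(is.finite(ov$conversion$conv_mean))
  # between-strata tests match direct calls
  expect_equal(rep$strata$overall$paired_rank$p.value,
               paired_rank_test(pairs$pmsa, pairs$pms_insp)$p.value)
  expect_equal(rep$between$pmsa$p.value,
               unpaired_rank_test(pairs$pmsa[1:8], pairs$pmsa[9:18])$p.value)
  expect_output(print(rep), "ICC")
})

test_that("run_study degrades gracefully on tiny cohorts and rejects duplicates", {
  one <- run_study(data.frame(pmsa = 11, pms_insp = 12))
  expect_equal(one$strata$overall$n, 1)
  expect_null(one$strata$overall$bland_altman)
  expect_true(any(grepl("descriptive", one$findings$finding)))
  expect_error(run_study(data.frame(patient_id = c("a", "a"),
                                    pmsa = c(1, 2), pms_insp = c(1, 2))),
               class = "pms_data_format")
  expect_error(run_study(data.frame(pmsa = numeric(), pms_insp = numeric())),
               class = "pms_insufficient_data")
})
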