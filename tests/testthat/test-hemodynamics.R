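test_that("Du Bois BSA matches direct evaluation and rejects degenerate input", {
  expect_equal(du_bois_bsa(176, 86), 0.007184 * 176^0.725 * 86^0.425)
  expect_equal(du_bois_bsa(176, 86), 2.0255, tolerance = 1e-4)
  expect_error(du_bois_bsa(0, 70), class = "pms_invalid_argument")
  expect_error(du_bois_bsa(170, -1), class = "pms_invalid_argument")
})

test_that("anthropometric constant matches hand computation", {
  # numerator 0.038 * (94.17 + 0.193*63); denominator 4.5 * 0.99^48 * BSA
  expect_equal(anthropometric_constant(63, 176, 86),
               0.038 * 106.329 / (4.5 * 0.99^48 * du_bois_bsa(176, 86)))
  expect_equal(anthropometric_constant(63, 176, 86), 0.718, tolerance = 1e-3)
  expect_equal(anthropometric_constant(15, 180, 80), 0.4106, tolerance = 1e-3)
})

test_that("age decay term is exactly 1 at age 15 and ages below 15 are rejected", {
  c15 <- anthropometric_constant(15, 180, 80)
  expect_equal(c15, 0.038 * (94.17 + 0.193 * 15) / (4.5 * du_bois_bsa(180, 80)))
  expect_error(anthropometric_constant(14.9, 180, 80), class = "pms_domain_error")
})

test_that("anthropometric constant is decreasing in body size and positive over ages", {
  h <- seq(150, 200, by = 5)
  expect_true(all(diff(anthropometric_constant(60, h, 80)) < 0))
  w <- seq(50, 120, by = 5)
  expect_true(all(diff(anthropometric_constant(60, 175, w)) < 0))
  ages <- seq(15, 120, by = 1)
  expect_true(all(anthropometric_constant(ages, 175, 80) > 0))
})

test_that("Pmsa reproduces hand-computed values and degenerate cases", {
  cc <- anthropometric_constant(63, 176, 86)
  expect_equal(pmsa(0, 0, 0, cc), 0)
  expect_equal(pmsa(10, 10, 0, cc), 10)  # pressure weights sum to 1
  expect_equal(pmsa(4.40, 69, 5.35, cc), 10.83, tolerance = 1e-2)
  expect_error(pmsa(5, 70, -1, cc), class = "pms_invalid_argument")
  expect_error(pmsa(5, 70, 5, 0), class = "pms_invalid_argument")
  expect_error(pmsa(5, 70, numeric(0), cc), class = "pms_invalid_argument")
})

test_that("Pmsa is linear and monotone nondecreasing in each input", {
  cc <- 0.7
  base <- pmsa(5, 70, 5, cc)
  for (d in c(0.5, 1, 3)) {
    expect_gt(pmsa(5 + d, 70, 5, cc), base)
    expect_gt(pmsa(5, 70 + d, 5, cc), base)
    expect_gt(pmsa(5, 70, 5 + d, cc), base)
  }
  # linearity: finite differences are constant
  expect_equal(pmsa(6, 70, 5, cc) - base, pmsa(7, 70, 5, cc) - pmsa(6, 70, 5, cc))
  expect_equal(pmsa(5, 70, 6, cc) - base, cc)
  expect_equal(pmsa(6, 70, 5, cc) - base, 0.96)
  expect_equal(pmsa(5, 71, 5, cc) - base, 0.04)
})

test_that("pVR is the Pms - RAP gradient and vanishes at zero flow with MAP = RAP", {
  cc <- 0.7
  p <- pmsa(6, 6, 0, cc)
  expect_equal(pvr(p, 6), 0)
  p2 <- pmsa(5, 70, 5, cc)
  expect_equal(pvr(p2, 5), p2 - 5)
  expect_gte(pvr(p2, 5), 0)
})

test_that("cohort Pmsa derives CO from CI and flags CO/CI disagreement", {
  coh <- data.frame(patient_id = c("a", "b"), age_y = c(60, 70),
                    height_cm = c(176, 160), weight_kg = c(86, 70),
                    rap_mmHg = c(4.4, 6), map_mmHg = c(69, 75),
                    ci_lminm2 = c(2.65, 2.2))
  out <- pmsa_cohort(coh)
  cc <- anthropometric_constant(60, 176, 86)
  expect_equal(out$pmsa_mmHg[1],
               pmsa(4.4, 69, 2.65 * du_bois_bsa(176, 86), cc))
  expect_equal(out$pvr_mmHg, out$pmsa_mmHg - coh$rap_mmHg)
  coh$co_lmin <- out$bsa_m2 * coh$ci_lminm2 * c(1.2, 1)  # 20% off for patient a
  expect_warning(pmsa_cohort(coh), class = "pms_unit_warning")
  coh$co_lmin <- out$bsa_m2 * coh$ci_lminm2 * 1.03       # inside 5% tolerance
  expect_silent(pmsa_cohort(coh))
})

test_that("realtime Pmsa is constant on a constant stream and lags a step by the window", {
  cc <- 0.7
  st <- data.frame(time = 0:199, rap = 5, map = 70, co = 5)
  rt <- pmsa_realtime(st, cc, window = 30)
  expect_equal(rt$pmsa, rep(pmsa(5, 70, 5, cc), 200))
  # step change at t = 100
  st2 <- st
  st2$rap[st2$time >= 100] <- 8
  rt2 <- pmsa_realtime(st2, cc, window = 30)
  lo <- pmsa(5, 70, 5, cc); hi <- pmsa(8, 70, 5, cc)
  expect_equal(rt2$pmsa[rt2$time == 99], lo)
  # still converging within the window, fully converged after it
  expect_lt(rt2$pmsa[rt2$time == 110], hi)
  expect_equal(rt2$pmsa[rt2$time == 130], hi)
  expect_true(all(diff(rt2$pmsa) >= -1e-9))  # nondecreasing up to cumsum rounding
})

test_that("realtime Pmsa rejects empty or broken streams", {
  expect_error(pmsa_realtime(data.frame(time = numeric(), rap = numeric(),
                                        map = numeric(), co = numeric()), 0.7),
               class = "pms_data_format")
  st <- data.frame(time = 0:9, rap = 5, map = 70, co = 5)
  st$co[4] <- NA
  expect_error(pmsa_realtime(st, 0.7), class = "pms_data_format")
})

test_that("pre-hold Pmsa is the smoothed value just before the tagged window", {
  cc <- 0.7
  st <- data.frame(time = 0:99, rap = 5, map = 70, co = 5)
  st$rap[st$time >= 50] <- 9  # hold raises RAP from t = 50
  rt <- pmsa_realtime(st, cc, window = 10)
  pre <- pmsa_before_holds(rt, data.frame(start = 50, end = 62, pplateau = 10))
  expect_equal(pre$pmsa, pmsa(5, 70, 5, cc))
  expect_error(pmsa_before_holds(rt, data.frame(start = -5, end = 12)),
               class = "pms_data_format")
})
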