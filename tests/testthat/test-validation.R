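test_that("an exact line is fit with r^2 = 1 and degenerate intervals", {
  d <- data.frame(conc = c(1, 2, 4, 8, 16), area = 2 * c(1, 2, 4, 8, 16) + 1)
  fit <- fit_calibration(d)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(diff(fit$ci_intercept), 0, tolerance = 1e-10)
  expect_error(fit_calibration(data.frame(conc = rep(1, 4),
                                          area = 1:4)), "levels")
})

test_that("intercept CI covers a true zero intercept near the nominal 95% rate", {
  hits <- vapply(1:400, function(s) {
    d <- gen_validation_data("calibration", intercept = 0, slope = 67.6,
                             sd = 3, seed = s)
    ci <- fit_calibration(d)$ci_intercept
    ci[1] <= 0 && ci[2] >= 0
  }, logical(1))
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.985)
})

test_that("a clearly nonzero slope is detected by its t-test", {
  p <- vapply(1:50, function(s) {
    d <- gen_validation_data("calibration", slope = 67.6, sd = 5, seed = s)
    fit_calibration(d)$p_slope
  }, numeric(1))
  expect_true(all(p < 0.05))
})

test_that("per-level replicate %RSD is screened against the 5% rule", {
  set.seed(11)
  d <- gen_validation_data("calibration", sd = 0.2, seed = 11)
  fit <- fit_calibration(d)
  expect_true(all(c("conc", "rsd_pct", "pass") %in% names(fit$level_rsd)))
  # noise sd 0.2 on areas >= 1.35 keeps every level under 5% RSD... except
  # possibly the lowest; the screen itself must flag exactly the violators
  expect_equal(fit$level_rsd$pass,
               is.na(fit$level_rsd$rsd_pct) | fit$level_rsd$rsd_pct <= 5)
})

test_that("Mandel's test distinguishes curvature from linearity", {
  x <- c(1, 2, 3, 4, 5, 6)
  quad <- mandel_test(data.frame(conc = x, area = x^2))
  expect_equal(quad$decision, "quadratic")
  expect_gt(quad$F, quad$f_critical * 10)

  lin <- mandel_test(data.frame(conc = x, area = 3 * x + 2))
  expect_equal(lin$decision, "linear")
  expect_equal(lin$F, 0)
})

test_that("the Mandel decision is invariant to affine rescaling of the response", {
  set.seed(5)
  d <- gen_validation_data("calibration", sd = 2, seed = 5)
  m1 <- mandel_test(d)
  d2 <- transform(d, area = 12.5 * area - 40)
  m2 <- mandel_test(d2)
  expect_equal(m2$decision, m1$decision)
  expect_equal(m2$F, m1$F, tolerance = 1e-8)
})

test_that("Cochran's C reproduces hand-computable statistics", {
  expect_equal(cochran_c(c(1, 1, 1, 1), 6)$C, 0.25)
  expect_equal(cochran_c(c(3, 1, 1, 1), 6)$C, 0.5)
  cc0 <- cochran_c(c(0, 0, 0), 6)
  expect_true(cc0$homogeneous)
  expect_error(cochran_c(1, 6), "2 groups")
})

test_that("precision components reproduce the two-cell worked examples", {
  # within-cell spread only: RSD_r = sqrt(2)/10, no between component
  d1 <- data.frame(day = rep(1:2, each = 2), level = "L",
                   value = c(9, 11, 9, 11))
  p1 <- precision_summary(d1)
  expect_equal(p1$rsd_r, sqrt(2) / 10 * 100, tolerance = 1e-10)
  expect_equal(p1$s_between2, 0)
  expect_equal(p1$rsd_R, p1$rsd_r)

  # between-cell spread only: RSD_r = 0, RSD_R = sqrt(2)/10
  d2 <- data.frame(day = rep(1:2, each = 2), level = "L",
                   value = c(9, 9, 11, 11))
  p2 <- precision_summary(d2)
  expect_equal(p2$rsd_r, 0)
  expect_equal(p2$s_between2, 2)
  expect_equal(p2$rsd_R, sqrt(2) / 10 * 100, tolerance = 1e-10)

  # identical determinations: both zero
  p3 <- precision_summary(data.frame(day = 1:2, level = "L",
                                     value = 5)[c(1, 1, 2, 2), ])
  expect_equal(p3$rsd_r, 0)
  expect_equal(p3$rsd_R, 0)

  expect_error(precision_summary(data.frame(day = 1:3, level = "L",
                                            value = 1:3)),
               "at least 2 replicates")
})

test_that("intermediate precision always dominates repeatability", {
  for (s in 1:20) {
    d <- gen_validation_data("precision", sd_day = runif(1, 0, 2),
                             sd_r = runif(1, 0.2, 2), seed = s)
    p <- precision_summary(d)
    expect_gte(p$rsd_R, p$rsd_r - 1e-12)
  }
})

test_that("Horwitz limits follow the closed form and the 2/3 repeatability rule", {
  h1 <- horwitz_limits(1)
  expect_equal(h1$rsd_R_max, 2)
  expect_equal(h1$rsd_r_max, 4 / 3)
  h2 <- horwitz_limits(1e-3)
  expect_equal(h2$rsd_R_max, 2^2.5)
  for (C in 10^seq(-6, 0)) {
    h <- horwitz_limits(C)
    expect_equal(h$rsd_r_max, 2 / 3 * h$rsd_R_max)
  }
  # limits decrease as concentration rises
  expect_lt(horwitz_limits(1e-2)$rsd_R_max, horwitz_limits(1e-4)$rsd_R_max)
  expect_error(horwitz_limits(0), "positive")
  expect_equal(round(rsd_r_from_rsd_R(5.68), 2), 3.79)
})

test_that("recovery statistics summarize level means with the three acceptance flags", {
  r <- recovery_stats(data.frame(level = c(75, 100, 125),
                                 recovery = c(101.41, 100.10, 99.96)))
  expect_equal(round(r$mean, 2), 100.49)
  expect_true(r$pass[["mean_in_98_102"]])

  perfect <- recovery_stats(data.frame(level = c(75, 100, 125),
                                       recovery = c(100, 100, 100)),
                            rsd_r_reference = 1)
  expect_equal(perfect$mean, 100)
  expect_equal(perfect$rsd_pct, 0)
  expect_true(all(unlist(perfect$pass)))

  # replicate-level input: mean over raw replicates, not level means
  set.seed(2)
  raw <- gen_validation_data("recovery", true_recovery = 100, sd = 0.5,
                             seed = 2)
  rr <- recovery_stats(raw)
  expect_equal(rr$mean, mean(raw$recovery))
  expect_equal(rr$n, nrow(raw))
})

test_that("detection limits follow 3.3/10 sigma over slope or empirical thresholds", {
  # construct a fit with known sigma via a calibration with noise
  d <- data.frame(conc = rep(c(1, 2, 4, 8, 16), each = 2))
  set.seed(9)
  d$area <- 10 * d$conc + rnorm(nrow(d), 0, 0.5)
  fit <- fit_calibration(d)
  lim <- detection_limits(fit = fit)
  expect_equal(lim$lod, 3.3 * fit$sigma_intercept / fit$slope)
  expect_equal(lim$loq, 10 * fit$sigma_intercept / fit$slope)
  expect_equal(lim$loq / lim$lod, 10 / 3.3)

  ser <- data.frame(conc = c(0.1, 0.2, 0.4, 0.8),
                    sn = c(2, 4, 9, 20),
                    rsd_pct = c(9, 7, 4.5, 2))
  le <- detection_limits(series = ser)
  expect_equal(le$lod, 0.2)   # lowest level with S/N > 3
  expect_equal(le$loq, 0.4)   # lowest level with %RSD <= 5
  expect_error(detection_limits(), "exactly one")
})

test_that("calibration-based LoD tracks the true error level across seeds", {
  sigma_true <- 2
  lods <- vapply(1:200, function(s) {
    d <- gen_validation_data("calibration", slope = 10, sd = sigma_true,
                             levels = c(1, 2, 4, 8, 16, 32), n_rep = 3,
                             seed = s)
    detection_limits(fit = fit_calibration(d))$lod
  }, numeric(1))
  # sigma of the intercept is sigma_true * sqrt(1/n + xbar^2/Sxx); compute
  # the design constant once and compare the mean LoD against it
  conc <- rep(c(1, 2, 4, 8, 16, 32), each = 3)
  kdes <- sqrt(1 / length(conc) + mean(conc)^2 /
                 sum((conc - mean(conc))^2))
  expect_equal(mean(lods), 3.3 * sigma_true * kdes / 10, tolerance = 0.1)
})
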