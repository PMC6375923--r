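test_that("noise-free responses from a known quadratic are refit to machine precision", {
  for (m in published_models()) {
    d <- gen_ccd_study(m, noise_sd = 0)
    fit <- fit_quadratic(d, "y")
    expect_equal(fit$coefficients, m$coefficients, tolerance = 1e-10)
    # and the fitted surface agrees with the truth everywhere on the region
    pts <- as.matrix(expand.grid(seq(-1.4, 1.4, 0.35),
                                 seq(-1.4, 1.4, 0.35)))
    expect_equal(predict_surface(fit, pts), predict_surface(m, pts),
                 tolerance = 1e-9)
  }
})

test_that("a constant response fits as pure intercept", {
  d <- build_central_composite(ccd_spec(2, n_center = 3))
  d <- set_response(d, "y", rep(5, nrow(d)))
  fit <- fit_quadratic(d, "y")
  expect_equal(unname(fit$coefficients["(Intercept)"]), 5)
  expect_equal(unname(fit$coefficients[-1]), rep(0, 5), tolerance = 1e-12)
})

test_that("coefficient confidence intervals have close to nominal coverage", {
  truth <- quadratic_model(1737.8, c(-106.1, 43.8), c(-86.9, -6.8), 47.3)
  hits <- vapply(1:300, function(s) {
    d <- gen_ccd_study(truth, noise_sd = 30, seed = s)
    fit <- fit_quadratic(d, "y")
    tcrit <- qt(0.975, fit$df_residual)
    all(abs(fit$coefficients - truth$coefficients) <= tcrit * fit$se)
  }, logical(1))
  # joint coverage of all 6 intervals; each is 95% so the joint rate is
  # lower — just require it stays in a plausible band
  expect_gt(mean(hits), 0.6)
  # marginal coverage of the intercept alone should be near 95%
  hit_b0 <- vapply(1:300, function(s) {
    d <- gen_ccd_study(truth, noise_sd = 30, seed = s)
    fit <- fit_quadratic(d, "y")
    abs(fit$coefficients[1] - 1737.8) <=
      qt(0.975, fit$df_residual) * fit$se[1]
  }, logical(1))
  expect_gt(mean(hit_b0), 0.90)
  expect_lt(mean(hit_b0), 0.99)
})

test_that("surface evaluation at the origin returns the intercept and sums coefficients at (1,1)", {
  m <- published_models()$TF
  expect_equal(predict_surface(m, c(0, 0)), 1737.8)
  expect_equal(predict_surface(m, c(1, 1)),
               1737.8 - 106.1 + 43.8 - 86.9 - 6.8 + 47.3)
  expect_error(predict_surface(m, c(0, 0, 0)), "coordinates")
})

test_that("the grid optimizer matches the closed-form interior stationary point", {
  fl <- published_models()$FL
  xs <- stationary_point(fl)
  expect_equal(unname(xs), c(0.2080, 0.5495), tolerance = 1e-3)
  opt <- optimize_response(fl, shape = "disk")
  expect_equal(unname(opt$coded), unname(xs), tolerance = 0.01)
  expect_equal(opt$predicted, predict_surface(fl, xs), tolerance = 1e-4)

  # concave bowl peaks at the origin
  bowl <- quadratic_model(0, c(0, 0), c(-1, -1), 0)
  expect_equal(unname(optimize_response(bowl)$coded), c(0, 0),
               tolerance = 1e-6)
})

test_that("a surface without interior maximum is optimized on the region boundary", {
  tf <- published_models()$TF
  opt <- optimize_response(tf, shape = "square", radius = 1.414)
  expect_true(any(abs(abs(opt$coded) - 1.414) < 1e-6))
  # brute-force grid oracle
  g <- as.matrix(expand.grid(seq(-1.414, 1.414, 0.01),
                             seq(-1.414, 1.414, 0.01)))
  expect_gte(opt$predicted + 1e-6, max(predict_surface(tf, g)))
})

test_that("desirability optimum is invariant to positive affine rescaling of a response", {
  ms <- published_models()
  opt1 <- optimize_response(unname(ms), mode = "desirability")
  scaled <- ms
  b <- scaled$CA$coefficients * 3.7
  b[1] <- b[1] + 250
  scaled$CA <- quadratic_model(b[1], b[2:3], b[4:5], b[6])
  opt2 <- optimize_response(unname(scaled), mode = "desirability")
  expect_equal(opt2$coded, opt1$coded, tolerance = 1e-6)
  expect_equal(opt2$desirability, opt1$desirability, tolerance = 1e-9)
})

test_that("constant responses return the origin with a warning", {
  flat <- quadratic_model(3, c(0, 0), c(0, 0), 0)
  expect_warning(opt <- optimize_response(flat), "constant")
  expect_equal(unname(opt$coded), c(0, 0))
})

test_that("verification t-test behaves at its edges and on the published summaries", {
  v0 <- verify_optimum(10, 1, 10, 1, 3)
  expect_equal(v0$t, 0)
  expect_equal(v0$p_value, 1)
  vz <- verify_optimum(10, 0, 10, 0, 3)
  expect_equal(vz$p_value, 1)

  ca <- verify_optimum(356.6, 3.6, 354.4, 3.2, 3)
  expect_gt(ca$p_value, 0.05)
  expect_equal(ca$percent_difference, abs(356.6 - 354.4) / 356.6 * 100)
  expect_equal(round(ca$percent_difference, 2), 0.62)

  # all three published verification rows are statistically indistinguishable
  tab <- read.csv(system.file("extdata", "verification_summary.csv",
                              package = "phenoval"))
  for (i in seq_len(nrow(tab))) {
    v <- verify_optimum(tab$predicted_mean[i], tab$predicted_sd[i],
                        tab$experimental_mean[i], tab$experimental_sd[i],
                        tab$n_experimental[i])
    expect_gt(v$p_value, 0.05)
  }
})

test_that("prediction standard errors are available only for fitted models", {
  m <- published_models()$CA
  expect_error(predict_surface(m, c(0, 0), se = TRUE), "literal")
  d <- gen_ccd_study(m, noise_sd = 1, seed = 7)
  fit <- fit_quadratic(d, "y")
  pr <- predict_surface(fit, c(0, 0), se = TRUE)
  expect_gt(pr$se_fit, 0)
})
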