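test_that("group summaries match the closed-form t interval", {
  s <- summarize_group(c(-4, -8, -12), baseline_sd = 6.4)
  # t(0.975, 2) = 4.302652729911..., sd = 4, n = 3
  half <- 4.302652729911 * 4 / sqrt(3)
  expect_equal(s$mean, -8)
  expect_equal(s$sd, 4)
  expect_equal(s$median, -8)
  expect_equal(s$ci_low, -8 - half, tolerance = 1e-9)
  expect_equal(s$ci_high, -8 + half, tolerance = 1e-9)
  expect_equal(s$srm, -2)
  expect_equal(s$ses * 6.4, s$mean, tolerance = 1e-12)
})

test_that("degenerate groups report undefined statistics honestly", {
  s <- summarize_group(c(-8, -8, -8))
  expect_equal(s$mean, -8)
  expect_equal(s$sd, 0)
  expect_equal(s$median, -8)
  expect_true(is.na(s$srm))
  expect_equal(s$ci_low, -8)  # zero-width interval at SD 0
  one <- summarize_group(-5)
  expect_true(is.na(one$ci_low) && is.na(one$srm))
  expect_error(summarize_group(numeric(0)), "empty")
})

test_that("the confidence interval shrinks like one over root n", {
  base <- rep(c(-13, -3), 50)          # fixed spread, sd constant
  wide <- summarize_group(base)
  narrow <- summarize_group(rep(base, 4))
  w1 <- wide$ci_high - wide$ci_low
  w2 <- narrow$ci_high - narrow$ci_low
  expect_equal(w2 / w1, 0.5, tolerance = 0.02)
})

test_that("even-count medians are the midpoint of the central pair", {
  s <- summarize_group(c(-10, -8, -7, -1))
  expect_equal(s$median, -7.5)
})

test_that("regression fits recover exact lines and flag degenerate designs", {
  f <- suppressWarnings(fit_change_regression(c(0, 1, 2, 3), 1 + 2 * c(0, 1, 2, 3)))
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  flat <- suppressWarnings(fit_change_regression(c(0, 1, 2, 3), rep(4, 4)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$intercept, 4, tolerance = 1e-12)
  expect_error(fit_change_regression(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(fit_change_regression(1:2, 1:2), "at least 3")
})

test_that("regression recovers known coefficients within 3 standard errors", {
  set.seed(77)
  x <- rnorm(500, 20.7, 25.15)
  y <- -8 - 0.25 * x + rnorm(500, 0, 9)
  td <- tidy(fit_change_regression(x, y))
  expect_lt(abs(td$estimate[1] - (-8)) / td$std_error[1], 3)
  expect_lt(abs(td$estimate[2] - (-0.25)) / td$std_error[2], 3)
  gl <- glance(fit_change_regression(x, y))
  expect_equal(gl$n, 500L)
})

test_that("regression projection is the line evaluated at the anchor threshold", {
  expect_equal(project_regression_mct(0, 7, slope = -1)$value, -7)
  expect_equal(project_regression_mct(-8.00, 7, slope = -0.24)$value, -9.68,
               tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(50); y <- 1 - 2 * x + rnorm(50)
  f <- fit_change_regression(x, y)
  expect_equal(project_regression_mct(f, 0)$value, f$intercept)  # limit check
  expect_equal(project_regression_mct(f, 3)$value, f$intercept + 3 * f$slope)
})

test_that("the half-SD candidate is exactly linear in the change SD", {
  expect_equal(half_sd_mct(0)$value, 0)
  set.seed(3)
  s <- runif(20, 0, 30)
  expect_equal(half_sd_mct(2 * s[1])$value, 2 * half_sd_mct(s[1])$value)
  for (k in 1:20) {
    expect_equal(half_sd_mct(s[k], improvement_sign = 1)$value, s[k] / 2)
    expect_equal(half_sd_mct(s[k])$value, -s[k] / 2)
  }
  expect_error(half_sd_mct(-1))
})

test_that("triangulation pools candidates into median, mean, range and integer", {
  tri <- triangulate(c(-8.22, -8.30, -8.20, -9.69))
  expect_equal(tri$mean, -8.6025, tolerance = 1e-12)
  expect_equal(tri$median, -8.26, tolerance = 1e-12)
  expect_equal(tri$range, c(-9.69, -8.20))
  expect_equal(tri$recommended, -8L)

  solo <- triangulate(-5.6)
  expect_equal(solo$mean, solo$median)
  expect_equal(solo$recommended, -6L)

  same <- triangulate(c(-8, -8, -8))
  expect_equal(same$median, -8)
  expect_equal(abs(same$recommended), 8L)
  expect_error(triangulate(numeric(0)), "no candidates")
})

test_that("the recommended integer rounds the median half-away-from-zero", {
  expect_equal(triangulate(c(-8.5))$recommended, -9L)
  expect_equal(triangulate(c(-8.49))$recommended, -8L)
  expect_equal(triangulate(c(8.5))$recommended, 9L)
  expect_equal(triangulate(c(-8.09))$recommended, -8L)
})

test_that("triangulation is permutation-invariant and filterable", {
  set.seed(9)
  v <- round(rnorm(7, -8, 2), 2)
  a <- triangulate(v); b <- triangulate(sample(v))
  expect_equal(a$mean, b$mean)
  expect_equal(a$median, b$median)
  expect_equal(a$range, b$range)

  cands <- dplyr::bind_rows(
    half_sd_mct(11.26, n = 224),
    project_regression_mct(-8, 7, slope = -0.24, anchor = "eq_vas")
  )
  only_dist <- triangulate(cands, include = function(df) df$source == "half_sd")
  expect_equal(nrow(only_dist$candidates), 1L)
  expect_equal(only_dist$median, -5.63)
})

test_that("tidy and glance expose the candidate list and the verdict", {
  tri <- triangulate(c(-8.22, -9.69))
  expect_s3_class(tidy(tri), "tbl_df")
  gl <- glance(tri)
  expect_named(gl, c("n_candidates", "mean", "median", "min", "max", "recommended"))
  expect_equal(gl$n_candidates, 2L)
})
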