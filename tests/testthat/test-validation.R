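test_that("noiseless calibration recovers the exact line", {
  cal <- tibble::tibble(concentration = c(2, 4, 6, 8, 10, 12))
  cal$peak_area <- 100000 * cal$concentration + 500
  fit <- fit_calibration(cal)
  expect_equal(fit$slope, 100000, tolerance = 1e-9)
  expect_equal(fit$intercept, 500, tolerance = 1e-9)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)
  expect_equal(fit$linearity_f, Inf)
  expect_equal(fit$df, c(1L, 4L))
  expect_equal(fit$f_critical, qf(0.95, 1, 4))
})

test_that("calibration slope/intercept agree with closed-form expressions", {
  set.seed(41)
  for (i in 1:10) {
    dat <- sim_calibration_data(seq(2, 12, 2), slope = 117000,
                                intercept = 1100, replicates = 3,
                                noise_sd = 2000, seed = i)
    fit <- fit_calibration(dat, aggregate = "replicates")
    x <- dat$concentration
    y <- dat$peak_area
    slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(fit$slope, slope_cf, tolerance = 1e-10)
    expect_equal(fit$intercept, mean(y) - slope_cf * mean(x),
                 tolerance = 1e-10)
  }
})

test_that("calibration defaults to per-concentration means for the ANOVA", {
  dat <- sim_calibration_data(seq(2, 12, 2), 117762, 1167.7,
                              replicates = 3, noise_sd = 3000, seed = 2)
  fit_means <- fit_calibration(dat)
  expect_equal(fit_means$df, c(1L, 4L))
  fit_raw <- fit_calibration(dat, aggregate = "replicates")
  expect_equal(fit_raw$df, c(1L, 16L))
  expect_error(fit_calibration(tibble::tibble(concentration = c(1, 1, 1),
                                              peak_area = c(2, 3, 4))),
               class = "degopt_degenerate_design")
})

test_that("slope estimates are unbiased over repeated noisy calibrations", {
  slopes <- vapply(1:500, function(s) {
    fit_calibration(sim_calibration_data(seq(2, 12, 2), slope = 100,
                                         intercept = 5, replicates = 3,
                                         noise_sd = 7, seed = s))$slope
  }, numeric(1))
  # se of the mean slope: sd(slope_hat) / sqrt(500)
  se_one <- 7 / sqrt(3 * sum((seq(2, 12, 2) - 7)^2))
  expect_lt(abs(mean(slopes) - 100), 4 * se_one / sqrt(500))
})

test_that("coefficient t tests use explicit nulls and flag exact fits", {
  exact <- tibble::tibble(concentration = c(2, 4, 6, 8),
                          peak_area = 10 * c(2, 4, 6, 8) + 3)
  tt <- coefficient_t_tests(fit_calibration(exact), slope_null = 10,
                            intercept_null = 3)
  expect_true(all(tt$exact_fit))
  expect_true(all(is.na(tt$t_statistic)))

  noisy <- sim_calibration_data(seq(2, 12, 2), slope = 100, intercept = 0,
                                replicates = 3, noise_sd = 5, seed = 3)
  tt <- coefficient_t_tests(fit_calibration(noisy, "replicates"),
                            slope_null = 0, intercept_null = 0)
  expect_gt(abs(tt$t_statistic[tt$term == "slope"]), 10)
  expect_lt(tt$p_value[tt$term == "slope"], 0.001)
})

test_that("intercept t test holds its nominal size under a true-null line", {
  rejections <- vapply(1:400, function(s) {
    dat <- sim_calibration_data(seq(2, 12, 2), slope = 100, intercept = 0,
                                replicates = 3, noise_sd = 10, seed = 1000 + s)
    tt <- coefficient_t_tests(fit_calibration(dat, "replicates"),
                              slope_null = 100, intercept_null = 0)
    tt$p_value[tt$term == "intercept"] < 0.05
  }, logical(1))
  # binomial(400, 0.05): mean 0.05, sd ~0.011; stay within ~4 sd
  expect_gt(mean(rejections), 0.005)
  expect_lt(mean(rejections), 0.095)
})

test_that("detection limits follow the ICH 3.3/10 sigma-over-slope rule", {
  dl <- detection_limits(1, 10)
  expect_equal(dl$dl, 0.33)
  expect_equal(dl$ql, 1.0)
  zero <- detection_limits(0, 10)
  expect_equal(c(zero$dl, zero$ql), c(0, 0))
  set.seed(59)
  for (i in 1:10) {
    d <- detection_limits(rexp(1) * 1000, rexp(1) * 1e5)
    expect_equal(d$ql / d$dl, 10 / 3.3, tolerance = 1e-12)
  }
  expect_error(detection_limits(1, -2), class = "degopt_domain_error")
})

test_that("precision ANOVA reproduces the published day-grouped F values", {
  tabs <- precision_tables()
  p80 <- precision_anova(tabs[["80%"]])
  expect_equal(p80$bms, 0.00028, tolerance = 1e-2)
  expect_equal(p80$wms, 0.0009, tolerance = 1e-3)
  expect_equal(signif(p80$f_value, 4), 0.3086)
  p100 <- precision_anova(tabs[["100%"]])
  expect_equal(signif(p100$f_value, 4), 0.8396)
  p120 <- precision_anova(tabs[["120%"]])
  expect_equal(signif(p120$f_value, 4), 1.508)
  expect_equal(p80$f_critical, qf(0.95, 2, 6))
  expect_true(all(c(p80$f_value, p100$f_value, p120$f_value) < p80$f_critical))
})

test_that("precision ANOVA matches a brute-force sums-of-squares oracle", {
  set.seed(61)
  for (i in 1:20) {
    m <- matrix(rnorm(12, 10, 0.3), nrow = 3)  # 3 days x 4 replicates
    out <- precision_anova(m)
    grand <- mean(m)
    day_means <- rowMeans(m)
    ss_between <- 4 * sum((day_means - grand)^2)
    ss_within <- sum((m - day_means)^2)
    expect_equal(out$bms, ss_between / 2, tolerance = 1e-12)
    expect_equal(out$wms, ss_within / 9, tolerance = 1e-12)
    # decomposition of the total corrected SS
    expect_equal(out$bms * out$df1 + out$wms * out$df2,
                 sum((m - grand)^2), tolerance = 1e-12)
  }
})

test_that("degenerate and unbalanced precision tables are flagged", {
  same <- matrix(10, 3, 3)
  out <- precision_anova(same)
  expect_true(out$degenerate)
  expect_true(is.na(out$f_value))
  unbal <- tibble::tibble(day = c(1, 1, 1, 2, 2), value = rnorm(5))
  expect_error(precision_anova(unbal), class = "degopt_unbalanced_anova")
  expect_error(precision_anova(matrix(1:3, 1, 3)), class = "degopt_shape_error")
})

test_that("per-day summaries report mean, sd and % RSD", {
  s <- precision_summary(precision_tables()[["80%"]])
  expect_equal(s$mean, c(10.03, 10.03, 10.04), tolerance = 1e-3)
  expect_equal(s$rsd_pct, 100 * s$sd / s$mean)
})

test_that("recovery regression reports slope, intercept and % recovery", {
  perfect <- tibble::tibble(added = c(10, 12.5, 15), found = c(10, 12.5, 15))
  r <- recovery_regression(perfect)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$by_level$recovery_pct, rep(100, 3))

  level_means <- tibble::tibble(added = c(10, 12.5, 15),
                                found = c(10.033, 12.427, 14.050))
  r2 <- recovery_regression(level_means)
  expect_equal(r2$slope, 0.8034, tolerance = 1e-3)

  scaled <- dplyr::mutate(perfect, added = added * 3, found = found * 3)
  expect_equal(recovery_regression(scaled)$slope, r$slope, tolerance = 1e-12)
  expect_error(recovery_regression(tibble::tibble(added = c(1, 1),
                                                  found = c(1, 2))),
               class = "degopt_degenerate_design")
})

test_that("assay content converts areas to percent of label claim", {
  cal <- list(slope = 100000, intercept = 0)
  expect_equal(assay_content(100000 * 10, cal, 10), 100)
  expect_equal(assay_content(1.1 * 100000 * 10, cal, 10), 110)
  areas <- 100000 * 10 * 1.0128 * c(1, 1, 1)
  expect_equal(mean(assay_content(areas, cal, 10)), 101.28, tolerance = 1e-9)
  expect_error(assay_content(1, list(slope = -1, intercept = 0), 10),
               class = "degopt_domain_error")
})
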