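acid_model <- function() {
  fd_fit(fd_design(acid_factors_tbl()), acid_responses)
}

test_that("single-factor inversion reproduces the published surface values", {
  mod <- acid_model()
  expect_equal(invert_single_factor(mod, 10, "X3", c(X1 = 0, X2 = -1),
                                    rounding = "2dp"),
               0.98, tolerance = 1e-2)
  expect_equal(invert_single_factor(mod, 20, "X3", c(X1 = 0, X2 = 1),
                                    rounding = "2dp"),
               -1.2, tolerance = 1e-2)
})

test_that("inversion round-trips through prediction", {
  mod <- acid_model()
  set.seed(17)
  for (i in 1:20) {
    p <- runif(3, -1, 1)
    target <- predict(mod, p)
    sol <- invert_single_factor(mod, target, "X3",
                                c(X1 = p[1], X2 = p[2]))
    expect_equal(sol, p[3], tolerance = 1e-9)
    expect_equal(predict(mod, c(p[1], p[2], sol)), target, tolerance = 1e-9)
  }
})

test_that("inversion agrees with a bisection oracle on random models", {
  set.seed(29)
  des <- unit_design(3)
  for (i in 1:20) {
    y <- rnorm(8, 20, 6)
    mod <- fd_fit(des, y)
    fixed <- c(X1 = runif(1, -1, 1), X2 = runif(1, -1, 1))
    f <- function(x3) predict(mod, c(fixed[1], fixed[2], x3))
    lo <- -4; hi <- 4
    if (abs(f(hi) - f(lo)) < 1e-8) next  # flat slice, no root to find
    target <- runif(1, min(f(lo), f(hi)) + 0.01, max(f(lo), f(hi)) - 0.01)
    # brute-force bisection
    a <- lo; b <- hi
    if (f(a) > f(b)) { a <- hi; b <- lo }
    for (j in 1:60) {
      m <- (a + b) / 2
      if (f(m) < target) a <- m else b <- m
    }
    expect_equal(invert_single_factor(mod, target, "X3", fixed),
                 (a + b) / 2, tolerance = 1e-6)
  }
})

test_that("a flat slice raises a no-solution error", {
  des <- unit_design(3)
  mod <- fd_fit(des, rep(7, 8))  # no dependence on anything
  expect_error(invert_single_factor(mod, 10, "X3", c(X1 = 0, X2 = 0)),
               class = "degopt_no_solution")
})

test_that("surface table reproduces the published 5 x 4 slice to 2 dp", {
  mod <- acid_model()
  slice <- surface_table(mod, solve = "X3", grid_factor = "X2",
                         grid_levels = c(-1, -0.5, 0, 0.5, 1),
                         targets = c(5, 10, 15, 20), rounding = "2dp")
  published <- rbind(
    c(-1.55, 0.98, 3.52, 6.06),
    c(-2.51, -0.98, 0.55, 2.09),
    c(-2.92, -1.82, -0.73, 0.37),
    c(-3.15, -2.30, -1.44, -0.59),
    c(-3.30, -2.60, -1.90, -1.20)
  )
  wide <- tidyr::pivot_wider(slice[, c("grid_value", "target", "solved")],
                             names_from = "target", values_from = "solved")
  expect_equal(round(as.matrix(wide[, -1]), 2), published,
               ignore_attr = TRUE, tolerance = 1e-9)
  # out-of-domain solutions are retained and marked, not clipped
  expect_false(slice$in_domain[slice$grid_value == -1 & slice$target == 5])
  expect_true(slice$in_domain[slice$grid_value == -1 & slice$target == 10])
})

test_that("surface table handles symmetric and empty inputs", {
  mod <- acid_model()
  slice <- surface_table(mod, "X3", "X2", grid_levels = 0,
                         targets = mod$intercept)
  expect_equal(slice$solved, 0, tolerance = 1e-12)
  empty <- surface_table(mod, "X3", "X2", grid_levels = numeric(),
                         targets = c(5, 10))
  expect_equal(nrow(empty), 0)
})

test_that("choose_condition finds the published acid optimum", {
  mod <- acid_model()
  yt <- yates_analysis(acid_responses, rounding = "integer")
  mod <- set_significant_terms(mod, yt, c("X2", "X3"))
  cond <- choose_condition(mod, target = 10, rounding = "2dp")
  expect_equal(unname(cond$coded[1:2]), c(0, -1))
  expect_equal(unname(cond$coded[3]), 0.98, tolerance = 1e-2)
  expect_true(cond$in_domain)
  expect_equal(cond$predicted, 10, tolerance = 1e-6)
  # decoded: midpoint acid strength, low temperature, near-maximal time
  expect_equal(unname(cond$actual[1]), 0.055)
  expect_equal(unname(cond$actual[2]), 55)
  expect_gt(unname(cond$actual[3]), 59)
  expect_lte(unname(cond$actual[3]), 60)
})

test_that("choose_condition solves the alkali optimum at the midpoint slice", {
  mod <- fd_fit(fd_design(alkali_factors_tbl()), alkali_responses)
  yt <- yates_analysis(alkali_rounded)
  mod <- set_significant_terms(mod, yt, "X2")
  cond <- choose_condition(mod, target = 10)
  expect_equal(unname(cond$coded[c(1, 3)]), c(0, 0))
  expect_equal(unname(cond$coded[2]), (10 - 19.635) / 10.8775,
               tolerance = 1e-9)
  expect_equal(unname(cond$actual[2]), 56.4, tolerance = 1e-2)
  expect_equal(unname(cond$actual[1]), 0.055)
  expect_equal(unname(cond$actual[3]), 22.5)
})

test_that("choose_condition returns the origin for the mean response", {
  mod <- acid_model()
  cond <- choose_condition(mod, target = mod$intercept)
  expect_equal(unname(cond$coded), c(0, 0, 0), tolerance = 1e-12)
})

test_that("unachievable targets error with the achievable range", {
  mod <- acid_model()
  expect_error(choose_condition(mod, target = 90),
               class = "degopt_domain_error")
  err <- tryCatch(choose_condition(mod, target = 90), error = identity)
  expect_match(conditionMessage(err), "achievable range")
})

test_that("predicted/observed comparison summarises confirmation runs", {
  out <- compare_predicted_observed(10, c(9.8, 10.1, 10.3))
  expect_equal(out$mean_observed, 10.0667, tolerance = 1e-4)
  expect_equal(out$difference, 0.0667, tolerance = 1e-3)
  expect_equal(out$df, 2)
  same <- compare_predicted_observed(10, c(10, 10, 10))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_predicted_observed(10, numeric()),
               class = "degopt_input_error")
})

test_that("confirmation t test holds its size at the true optimum", {
  # replicates drawn at the true response: non-significant in >= 90% of runs
  n_sig <- 0L
  n_sims <- 1000L
  withr::with_seed(101, {
    for (i in seq_len(n_sims)) {
      obs <- rnorm(3, mean = 10, sd = 0.5)
      p <- compare_predicted_observed(10, obs)$p_value
      if (p < 0.05) n_sig <- n_sig + 1L
    }
  })
  expect_lt(n_sig / n_sims, 0.10)
})
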