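test_that("packaged case-study files load through the CSV readers", {
  fac <- chlorthalidone_factors("acid")
  expect_equal(fac$name, c("acid_strength", "temperature", "time"))
  expect_equal(fac$low, c(0.01, 55, 30))
  runs <- chlorthalidone_runs("acid")
  expect_equal(runs$response_pct, acid_responses)
  runs_alk <- chlorthalidone_runs("alkali")
  expect_equal(runs_alk$response_pct, alkali_responses)
  prec <- chlorthalidone_precision()
  expect_equal(nrow(prec), 27)
  expect_setequal(unique(prec$level), c("80%", "100%", "120%"))
})

test_that("end-to-end acid analysis reproduces the published summary", {
  report <- run_degradation_analysis(
    chlorthalidone_factors("acid"), chlorthalidone_runs("acid"),
    label = "acid", target = 10, f_critical = 98.49,
    yates_rounding = "integer", significant_terms = c("X2", "X3"),
    paper_rounding = TRUE
  )
  expect_match(report$equation, "^Y = 18.32 - 0.67 X1 \\+ 10.26 X2")
  expect_equal(report$r_squared_reduced, 0.9462, tolerance = 1e-4)
  expect_equal(attr(report$yates, "error_ms"), 0.25)
  expect_equal(unname(report$optimum$coded[1:2]), c(0, -1))
  expect_equal(unname(report$optimum$actual[1]), 0.055)
  expect_equal(unname(report$optimum$actual[2]), 55)
})

test_that("end-to-end alkali analysis solves the midpoint-slice optimum", {
  report <- run_degradation_analysis(
    chlorthalidone_factors("alkali"), chlorthalidone_runs("alkali"),
    label = "alkali", target = 10, f_critical = 98.49,
    significant_terms = "X2", paper_rounding = TRUE
  )
  # with the 2-dp equation: X2 = (10 - 19.64) / 10.88, others at midpoint
  expect_equal(unname(report$optimum$coded[2]), (10 - 19.64) / 10.88,
               tolerance = 1e-9)
  expect_equal(unname(report$optimum$actual[1]), 0.055)
  expect_equal(unname(report$optimum$actual[3]), 22.5)
  expect_equal(unname(report$optimum$actual[2]), 56.43, tolerance = 1e-3)
})

test_that("synthetic noiseless inputs flow through the pipeline unchanged", {
  fac <- tibble::tibble(name = c("A", "B", "C"), low = c(0, 0, 0),
                        high = c(1, 1, 1))
  des <- fd_design(fac)
  y <- sim_factorial_responses(des, 18.32, c(X2 = 10.26, X3 = 4.56),
                               noise_sd = 0, seed = 1)
  report <- run_degradation_analysis(fac, y |>
                                       dplyr::rename(response_pct = response),
                                     target = 10, alpha = 0.01)
  expect_equal(report$model$intercept, 18.32, tolerance = 1e-9)
  expect_equal(unname(report$model$coefficients["X2"]), 10.26,
               tolerance = 1e-9)
  expect_equal(predict(report$model, unname(report$optimum$coded)), 10,
               tolerance = 1e-6)
})

test_that("design CSV round-trips losslessly", {
  des <- fd_design(acid_factors_tbl())
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(des, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(unname(as.matrix(back[, 2:4])),
               unname(as.matrix(des$runs[, -1])))
  expect_equal(names(back),
               c("run", "acid_strength", "temperature", "time",
                 "X1X2", "X1X3", "X2X3", "X1X2X3"))
})

test_that("malformed run tables produce parse errors naming the cell", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("run,response_pct", "1,7.14", "2,oops"), path)
  err <- tryCatch(read_run_table(path), error = identity)
  expect_s3_class(err, "degopt_parse_error")
  expect_match(conditionMessage(err), "response_pct")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "oops")
  expect_error(read_factor_table(withr::local_tempfile(fileext = ".csv")),
               class = "degopt_io_error")
})

test_that("CRLF and LF run tables parse identically", {
  lf <- withr::local_tempfile(fileext = ".csv")
  crlf <- withr::local_tempfile(fileext = ".csv")
  lines <- c("run,response_pct", "1,7.14", "2,5.03")
  writeLines(lines, lf, sep = "\n")
  writeLines(lines, crlf, sep = "\r\n")
  expect_equal(as.data.frame(read_run_table(lf)),
               as.data.frame(read_run_table(crlf)))
})

test_that("reports are deterministic and written in full precision", {
  run_once <- function(dir) {
    report <- run_degradation_analysis(
      chlorthalidone_factors("acid"), chlorthalidone_runs("acid"),
      label = "acid", target = 10, f_critical = 98.49,
      yates_rounding = "integer", significant_terms = c("X2", "X3")
    )
    write_report(report, dir)
    report
  }
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_once(d1)
  run_once(d2)
  for (f in c("design.csv", "yates_report.csv", "pareto_report.csv",
              "model.json", "optimum.json", "report.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  model <- jsonlite::read_json(file.path(d1, "model.json"))
  expect_equal(model$intercept, 18.32375, tolerance = 1e-12)
  expect_equal(model$r_squared_reduced, (840.5 + 162) / 1059.5,
               tolerance = 1e-12)
})

test_that("pipeline validates the target range", {
  expect_error(run_degradation_analysis(acid_factors_tbl(), acid_run_tbl(),
                                        target = 0),
               class = "degopt_domain_error")
  expect_error(run_degradation_analysis(acid_factors_tbl(), acid_run_tbl(),
                                        target = 150),
               class = "degopt_domain_error")
})

test_that("an unattainable target is reported, not an error", {
  report <- run_degradation_analysis(acid_factors_tbl(), acid_run_tbl(),
                                     target = 99)
  expect_null(report$optimum)
  expect_match(report$optimum_error, "achievable range")
})
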