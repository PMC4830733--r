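#' Read a factor-specification CSV
#'
#' Expected columns: `name,low,high` and optionally `units`; UTF-8, comma
#' separated, `.` decimal separator, header required.  CRLF and LF line
#' endings are both accepted.
#'
#' @param path CSV file path.
#' @return A validated factor tibble, ready for [fd_design()].
#' @export
read_factor_table <- function(path) {
  dat <- read_checked_csv(path, numeric_cols = c("low", "high"))
  validate_factor_table(dat)
}

#' Read a run-table CSV
#'
#' Expected columns: `run`, optionally the coded factor columns, and either
#' `response_pct` or `area_unstressed` + `area_stressed`.
#'
#' @param path CSV file path.
#' @return A tibble of per-run records for [assemble_responses()].
#' @export
read_run_table <- function(path) {
  num <- c("run", "response_pct", "area_unstressed", "area_stressed")
  read_checked_csv(path, numeric_cols = num, required = "run")
}

#' Read a precision-table CSV
#'
#' Expected columns: `level`, `nominal_mg`, `day`, `replicate`, `found_mg`.
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_precision_table <- function(path) {
  read_checked_csv(path,
                   numeric_cols = c("nominal_mg", "day", "replicate", "found_mg"),
                   required = c("level", "day", "found_mg"))
}

# Shared CSV reader: header mandatory, '.' decimal, parse problems reported
# with their row and column.
read_checked_csv <- function(path, numeric_cols = character(), required = character()) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "degopt_io_error")
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(dat))
  if (length(miss)) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(miss, collapse = ", ")),
          class = "degopt_parse_error")
  }
  for (col in intersect(numeric_cols, names(dat))) {
    v <- dat[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        abort(sprintf("%s: column '%s', row %d: '%s' is not a number.",
                      path, col, bad[1], v[bad[1]]),
              class = "degopt_parse_error")
      }
      dat[[col]] <- parsed
    }
  }
  dat
}

#' Run the full degradation-optimization analysis
#'
#' Orchestrates the whole workflow on one stress system: build the 2^k
#' design, assemble % degradation responses, run the Yates analysis with a
#' pooled-error F screen, rank effects on the Pareto scale, fit the coded
#' polynomial, compute the reduced-model R-squared for the screened terms,
#' and solve for an in-domain condition attaining the target % degradation.
#' The result is fully determined by its inputs and settings.
#'
#' @param factors Factor table (see [fd_design()]) or path to a factors CSV.
#' @param runs Per-run records (see [assemble_responses()]) or path to a runs
#'   CSV.
#' @param label Optional label for the stress system (e.g. `"acid"`).
#' @param target Target % degradation for the optimization step (default 10).
#' @param pool_size,yates_rounding,f_critical,alpha Passed to
#'   [yates_analysis()] / [f_screen()].
#' @param significant_terms Explicit significant set for the reduced R-squared
#'   and the optimizer; default `NULL` uses the F-screen result.
#' @param paper_rounding If `TRUE`, surface arithmetic (the optimizer) uses
#'   the 2-dp rounded equation coefficients, the arithmetic used in published
#'   surface tables; default `FALSE` (full precision).
#' @return A list of class `degradation_report`: `design`, `responses`,
#'   `yates`, `significant`, `pareto`, `model`, `equation`,
#'   `r_squared_reduced`, `optimum` (or `NULL` if the target is unattainable,
#'   with the condition error stored in `optimum_error`), and `settings`.
#' @examples
#' report <- run_degradation_analysis(
#'   chlorthalidone_factors("acid"),
#'   chlorthalidone_runs("acid"),
#'   label = "acid", target = 10, f_critical = 98.49,
#'   yates_rounding = "integer", paper_rounding = TRUE
#' )
#' report$equation
#' @export
run_degradation_analysis <- function(factors, runs, label = NULL, target = 10,
                                     pool_size = 2L,
                                     yates_rounding = c("none", "integer"),
                                     f_critical = NULL, alpha = 0.01,
                                     significant_terms = NULL,
                                     paper_rounding = FALSE) {
  yates_rounding <- match.arg(yates_rounding)
  if (!is.numeric(target) || target <= 0 || target >= 100) {
    abort("`target` must be a % strictly between 0 and 100.",
          class = "degopt_domain_error")
  }
  if (is.character(factors)) factors <- read_factor_table(factors)
  if (is.character(runs)) runs <- read_run_table(runs)

  design <- fd_design(factors)
  responses <- assemble_responses(runs, design, label = label)
  yates <- yates_analysis(responses, pool_size = pool_size,
                          rounding = yates_rounding,
                          f_critical = f_critical, alpha = alpha)
  significant <- significant_terms %||% f_screen(yates)
  pareto <- pareto_squares(yates)
  model <- fd_fit(design, responses, label = label)
  if (length(significant)) {
    model <- set_significant_terms(model, yates, significant)
  }
  rounding <- if (paper_rounding) "2dp" else "full"
  optimum <- tryCatch(
    choose_condition(model, target = target, rounding = rounding),
    degopt_domain_error = function(e) e
  )
  optimum_error <- NULL
  if (inherits(optimum, "condition")) {
    optimum_error <- conditionMessage(optimum)
    optimum <- NULL
  }

  structure(
    list(design = design, responses = responses, yates = yates,
         significant = significant, pareto = pareto, model = model,
         equation = model_equation(model),
         r_squared_reduced = model$r_squared_reduced,
         optimum = optimum, optimum_error = optimum_error,
         settings = list(label = label, target = target,
                         pool_size = pool_size,
                         yates_rounding = yates_rounding,
                         f_critical = attr(yates, "f_critical"),
                         alpha = alpha,
                         significant_terms = significant,
                         paper_rounding = paper_rounding)),
    class = "degradation_report"
  )
}

#' @export
print.degradation_report <- function(x, ...) {
  cat("== Degradation optimization report",
      if (!is.null(x$settings$label)) paste0("[", x$settings$label, "]"), "==\n")
  cat("Equation: ", x$equation, "\n")
  cat("Significant terms (F >", format(x$settings$f_critical), "):",
      if (length(x$significant)) paste(x$significant, collapse = ", ") else "none", "\n")
  if (!is.null(x$r_squared_reduced)) {
    cat(sprintf("Reduced-model R^2 = %.4f\n", x$r_squared_reduced))
  }
  if (!is.null(x$optimum)) {
    print(x$optimum)
  } else if (!is.null(x$optimum_error)) {
    cat("Optimum: ", x$optimum_error, "\n")
  }
  invisible(x)
}

#' Write a degradation report to disk
#'
#' Writes `design.csv`, `yates_report.csv`, `pareto_report.csv`,
#' `model.json`, `optimum.json` (if an optimum was found) and a combined
#' `report.json` with full-precision numbers into a directory.  The files are
#' fully regenerable from the inputs and settings; nothing is hand-edited.
#'
#' @param report A [run_degradation_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "degradation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_design_csv(report$design, file.path(dir, "design.csv"))
  readr::write_csv(as_tibble(report$yates), file.path(dir, "yates_report.csv"))
  readr::write_csv(as_tibble(report$pareto), file.path(dir, "pareto_report.csv"))

  model_json <- list(
    label = report$settings$label,
    intercept = report$model$intercept,
    coefficients = as.list(report$model$coefficients),
    significant_terms = as.list(report$significant),
    r_squared_reduced = report$r_squared_reduced,
    equation = report$equation
  )
  jsonlite::write_json(model_json, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$optimum)) {
    opt <- report$optimum
    jsonlite::write_json(
      list(coded = as.list(opt$coded), actual = as.list(opt$actual),
           units = as.list(setNames(opt$units, names(opt$coded))),
           predicted = opt$predicted, target = opt$target,
           in_domain = opt$in_domain),
      file.path(dir, "optimum.json"), auto_unbox = TRUE, digits = NA)
  }
  combined <- list(
    settings = report$settings,
    model = model_json,
    error_ms = attr(report$yates, "error_ms"),
    error_df = attr(report$yates, "error_df"),
    pooled_terms = as.list(attr(report$yates, "pooled_terms")),
    optimum_error = report$optimum_error
  )
  jsonlite::write_json(combined, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
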