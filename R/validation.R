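# A sum of squares that is zero in exact arithmetic comes out as ~1e-30
# floating-point residue; clamp anything below the double-precision noise
# floor of the data's scale to an exact zero.
zap_ss <- function(ss, values) {
  tol <- (max(abs(values), 1e-300) * 1e-10)^2
  if (ss <= tol) 0 else ss
}

#' Fit a calibration curve with linearity ANOVA
#'
#' Least-squares regression of peak area on concentration, with the linearity
#' F test (regression mean square over residual mean square).  By default the
#' regression and ANOVA are computed on per-concentration mean responses, so
#' with m distinct concentrations the F test has (1, m - 2) degrees of
#' freedom; set `aggregate = "replicates"` to use all raw points instead.
#'
#' @param points A data frame with columns `concentration` (e.g. ug/mL) and
#'   `peak_area`, optionally `replicate`.
#' @param aggregate `"means"` (default) or `"replicates"`.
#' @return An object of class `calibration_fit`: list with `slope`,
#'   `intercept`, `correlation` (Pearson r of the aggregation level),
#'   `linearity_f`, `df` (c(1, residual df)), `f_critical` (5% point),
#'   `residual_sd`, `fit` (the underlying [lm] object), `data` and `level`
#'   (aggregation level used).  With an exact line the residual MS is 0 and
#'   `linearity_f` is `Inf` (exceeds any critical value).
#' @examples
#' cal <- tibble::tibble(concentration = c(2, 4, 6, 8, 10, 12),
#'                       peak_area = 100000 * c(2, 4, 6, 8, 10, 12) + 500)
#' fit_calibration(cal)
#' @export
fit_calibration <- function(points, aggregate = c("means", "replicates")) {
  aggregate <- match.arg(aggregate)
  if (!is.data.frame(points) ||
      !all(c("concentration", "peak_area") %in% names(points))) {
    abort("`points` must have columns `concentration` and `peak_area`.",
          class = "degopt_shape_error")
  }
  points <- as_tibble(points)
  if (dplyr::n_distinct(points$concentration) < 3L) {
    abort("At least 3 distinct concentrations are required.",
          class = "degopt_degenerate_design")
  }
  dat <- if (aggregate == "means") {
    dplyr::summarise(dplyr::group_by(points, .data$concentration),
                     peak_area = mean(.data$peak_area), .groups = "drop")
  } else {
    points
  }
  fit <- lm(peak_area ~ concentration, data = dat)
  res_df <- stats::df.residual(fit)
  res_ss <- sum(stats::residuals(fit)^2)
  reg_ss <- sum((stats::fitted(fit) - mean(dat$peak_area))^2)
  # sums of squares below the floating-point noise floor are exact zeros
  res_ms <- zap_ss(res_ss, dat$peak_area) / res_df
  reg_ms <- reg_ss  # 1 df
  linearity_f <- if (res_ms > 0) reg_ms / res_ms else Inf

  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         correlation = stats::cor(dat$concentration, dat$peak_area),
         linearity_f = linearity_f, df = c(1L, res_df),
         f_critical = qf(0.95, 1, res_df),
         residual_sd = sqrt(res_ms), fit = fit,
         data = points, level = aggregate),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> y = %.6g x %+.6g  (r = %.4f)\n",
              x$slope, x$intercept, x$correlation))
  cat(sprintf("  linearity F(%d, %d) = %.6g (5%% critical %.3g)\n",
              x$df[1], x$df[2], x$linearity_f, x$f_critical))
  invisible(x)
}

#' @export
tidy.calibration_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$correlation,
         linearity_f = x$linearity_f, df_residual = x$df[2],
         residual_sd = x$residual_sd)
}

#' t tests of calibration slope and intercept against stated nulls
#'
#' Two-sided one-sample t tests `t = (estimate - null) / SE` with n - 2
#' degrees of freedom, at the regression's aggregation level.  The null values
#' are explicit arguments — typically 0 for the intercept (no bias at zero
#' concentration); the slope null depends on what is being checked.
#'
#' @param curve A [fit_calibration()] result.
#' @param slope_null,intercept_null Null values to test against.
#' @return A tibble with one row per coefficient: `term`, `estimate`, `null`,
#'   `std_error`, `t_statistic`, `df`, `p_value`, `exact_fit`.  With zero
#'   residual variance the t statistics are undefined and `exact_fit` is
#'   `TRUE`.
#' @export
coefficient_t_tests <- function(curve, slope_null = 0, intercept_null = 0) {
  stopifnot(inherits(curve, "calibration_fit"))
  est <- coef(curve$fit)
  df <- curve$df[2]
  exact <- curve$residual_sd == 0
  se <- if (exact) rep(NA_real_, 2) else summary(curve$fit)$coefficients[, 2]
  null <- c(intercept_null, slope_null)
  tstat <- if (exact) rep(NA_real_, 2) else (est - null) / se
  pval <- if (exact) rep(NA_real_, 2) else 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tibble(term = c("intercept", "slope"), estimate = unname(est),
         null = null, std_error = unname(se),
         t_statistic = unname(tstat), df = df, p_value = unname(pval),
         exact_fit = exact)
}

#' ICH Q2 detection and quantitation limits
#'
#' `DL = 3.3 * sigma / S` and `QL = 10 * sigma / S`, where `sigma` is a
#' standard deviation of the response (residual SD of the calibration by
#' convention here; the SD of the intercept is an accepted alternative) and
#' `S` the calibration slope.  The ratio QL/DL is 10/3.3 by construction.
#'
#' @param response_sd Standard deviation of the response (area units), >= 0.
#' @param slope Calibration slope (> 0), or a [fit_calibration()] object from
#'   which both the residual SD and slope are taken.
#' @return A one-row tibble: `response_sd`, `slope`, `dl`, `ql`
#'   (concentration units of the calibration).
#' @examples
#' detection_limits(1, 10)  # dl 0.33, ql 1.0
#' @export
detection_limits <- function(response_sd, slope = NULL) {
  if (inherits(response_sd, "calibration_fit")) {
    slope <- response_sd$slope
    response_sd <- response_sd$residual_sd
  }
  if (!is.numeric(response_sd) || response_sd < 0) {
    abort("`response_sd` must be >= 0.", class = "degopt_domain_error")
  }
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    abort("`slope` must be a single positive number.", class = "degopt_domain_error")
  }
  tibble(response_sd = response_sd, slope = slope,
         dl = 3.3 * response_sd / slope, ql = 10 * response_sd / slope)
}

#' One-way ANOVA for intermediate precision (day-grouped)
#'
#' Balanced one-way analysis of variance with day as the grouping factor:
#' `F = BMS / WMS`, the ratio of the between-day mean square (days - 1 df) to
#' the within-day mean square (days * (replicates - 1) df).  An F below the
#' tabulated critical value indicates that between-day variability does not
#' exceed within-day variability, i.e. acceptable intermediate precision.
#'
#' @param values A data frame with columns `day` and `value` (amount found,
#'   mg), or a days-by-replicates numeric matrix.
#' @param alpha Significance level for the critical F (default 0.05).
#' @return A one-row tibble of class `precision_anova`: `days`, `replicates`,
#'   `bms`, `wms`, `f_value`, `df1`, `df2`, `f_critical`, `p_value`,
#'   `degenerate` (`TRUE` when all values are identical, making F undefined).
#' @examples
#' m <- rbind(day1 = c(10, 10.05, 10.03),
#'            day2 = c(10.02, 10.03, 10.03),
#'            day3 = c(10, 10.09, 10.04))
#' precision_anova(m)
#' @export
precision_anova <- function(values, alpha = 0.05) {
  if (is.matrix(values)) {
    values <- tibble(
      day = rep(seq_len(nrow(values)), times = ncol(values)),
      value = as.numeric(values)
    )
  }
  if (!is.data.frame(values) || !all(c("day", "value") %in% names(values))) {
    abort("`values` must be a matrix or a data frame with columns `day` and `value`.",
          class = "degopt_shape_error")
  }
  values <- as_tibble(values)
  counts <- table(values$day)
  days <- length(counts)
  if (days < 2L || any(counts < 2L)) {
    abort("Need >= 2 days with >= 2 replicates each.", class = "degopt_shape_error")
  }
  if (length(unique(as.integer(counts))) != 1L) {
    abort("Unbalanced day-by-replicate table; this ANOVA requires equal replicates per day.",
          class = "degopt_unbalanced_anova")
  }
  reps <- as.integer(counts[1])

  fit <- lm(value ~ factor(day), data = values)
  df1 <- days - 1L
  df2 <- stats::df.residual(fit)
  ss_within <- zap_ss(sum(stats::residuals(fit)^2), values$value)
  ss_between <- zap_ss(sum((stats::fitted(fit) - mean(values$value))^2),
                       values$value)
  bms <- ss_between / df1
  wms <- ss_within / df2
  degenerate <- bms == 0 && wms == 0
  f_value <- if (degenerate) NA_real_ else bms / wms  # Inf when wms == 0
  p_value <- if (degenerate) NA_real_ else stats::pf(f_value, df1, df2, lower.tail = FALSE)

  out <- tibble(days = days, replicates = reps, bms = bms, wms = wms,
                f_value = f_value, df1 = df1, df2 = df2,
                f_critical = qf(1 - alpha, df1, df2),
                p_value = p_value, degenerate = degenerate)
  structure(out, class = c("precision_anova", class(out)))
}

#' Per-day summary statistics for a precision table
#'
#' Mean, sample SD and % RSD (100 * sd / mean) per day.
#'
#' @inheritParams precision_anova
#' @return A tibble with columns `day`, `n`, `mean`, `sd`, `rsd_pct`.
#' @export
precision_summary <- function(values) {
  if (is.matrix(values)) {
    values <- tibble(day = rep(seq_len(nrow(values)), times = ncol(values)),
                     value = as.numeric(values))
  }
  dplyr::summarise(dplyr::group_by(as_tibble(values), .data$day),
                   n = dplyr::n(), mean = mean(.data$value),
                   sd = sd(.data$value),
                   rsd_pct = 100 * sd(.data$value) / mean(.data$value),
                   .groups = "drop")
}

#' Recovery regression and per-level recovery
#'
#' Least squares of amount found on amount added across fortification levels,
#' plus the per-level mean recovery `100 * mean(found) / added`.  A slope near
#' 1 and intercept near 0 indicate accuracy across the tested range.
#'
#' @param pairs A data frame with columns `added` and `found` (mg); replicate
#'   rows per level are allowed.
#' @return A list of class `recovery_fit`: `slope`, `intercept`, `fit`, and
#'   `by_level` (tibble: `added`, `n`, `mean_found`, `recovery_pct`).
#' @export
recovery_regression <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("added", "found") %in% names(pairs))) {
    abort("`pairs` must have columns `added` and `found`.",
          class = "degopt_shape_error")
  }
  if (dplyr::n_distinct(pairs$added) < 2L) {
    abort("At least 2 distinct added amounts are required.",
          class = "degopt_degenerate_design")
  }
  fit <- lm(found ~ added, data = pairs)
  by_level <- dplyr::summarise(
    dplyr::group_by(as_tibble(pairs), .data$added),
    n = dplyr::n(), mean_found = mean(.data$found),
    recovery_pct = 100 * mean(.data$found) / .data$added[1],
    .groups = "drop"
  )
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 fit = fit, by_level = by_level),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("<recovery_fit> found = %.4f * added %+.4f\n", x$slope, x$intercept))
  print(as.data.frame(x$by_level), row.names = FALSE)
  invisible(x)
}

#' Assay content as percent of label claim
#'
#' Converts a sample peak area to concentration through the calibration line
#' and expresses it against the nominal concentration:
#' `100 * ((area - intercept) / slope) / nominal_conc`.
#'
#' @param sample_area Peak area(s) of the assay preparation.
#' @param curve A [fit_calibration()] result (or a list with `slope` and
#'   `intercept`).
#' @param nominal_conc Nominal concentration of the preparation (> 0), in the
#'   calibration's concentration units.
#' @return Percent of label claim (vectorised over `sample_area`).
#' @export
assay_content <- function(sample_area, curve, nominal_conc) {
  slope <- curve$slope
  intercept <- curve$intercept
  if (!is.numeric(slope) || slope <= 0) {
    abort("Calibration slope must be positive.", class = "degopt_domain_error")
  }
  if (!is.numeric(nominal_conc) || nominal_conc <= 0) {
    abort("`nominal_conc` must be > 0.", class = "degopt_domain_error")
  }
  100 * ((sample_area - intercept) / slope) / nominal_conc
}
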