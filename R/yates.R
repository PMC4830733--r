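#' Yates transform of a standard-order response vector
#'
#' Applies k passes of the pairwise sum/difference operator to a 2^k response
#' vector in standard (Yates) order.  In each pass the first half of the new
#' column holds sums of consecutive pairs and the second half differences
#' (second minus first).  After k passes the column holds the factorial
#' contrasts: the total sum first, then one contrast per effect in standard
#' order (X1, X2, X1X2, X3, X1X3, X2X3, X1X2X3 for k = 3).  Each contrast
#' equals the dot product of the corresponding coded effect column with the
#' responses.
#'
#' @param responses Numeric vector of length 2^k (or anything accepted by
#'   [response_vector()]), in standard run order.
#' @param keep_stages If `TRUE`, return a matrix whose columns are the k
#'   intermediate passes (the "A", "B", "C" columns of a worked Yates table),
#'   with the contrasts in the last column.
#' @return Numeric vector of 2^k contrasts, or a 2^k x k matrix if
#'   `keep_stages = TRUE`.
#' @examples
#' yates_transform(c(7, 5, 23, 20, 10, 10, 36, 35))
#' @export
yates_transform <- function(responses, keep_stages = FALSE) {
  y <- response_vector(responses)
  n <- length(y)
  k <- as.integer(round(log2(n)))
  if (n < 2L || 2L^k != n) {
    abort("Yates transform needs a response vector whose length is a power of two (>= 2).",
          class = "degopt_shape_error")
  }
  stages <- matrix(NA_real_, n, k)
  cur <- y
  for (pass in seq_len(k)) {
    odd <- cur[seq(1L, n, by = 2L)]
    even <- cur[seq(2L, n, by = 2L)]
    cur <- c(even + odd, even - odd)
    stages[, pass] <- cur
  }
  if (keep_stages) stages else cur
}

# nearest integer, halves away from zero (so 0.5 -> 1, -0.5 -> -1), the
# convention a hand-worked Yates table uses
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Yates analysis: effects, mean squares and pooled-error F values
#'
#' Runs [yates_transform()] and derives, for every effect, the effect size
#' (contrast / 2^(k-1)), its mean square (contrast^2 / 2^k, 1 df each) and a
#' pooled-error F value.  In a saturated (unreplicated) full factorial there is
#' no residual to estimate error from, so the error mean square is formed by
#' pooling the `pool_size` smallest effect mean squares ("average least mean
#' square"); each F value is then `mean_square / error_ms` on (1, pool_size)
#' degrees of freedom.  Effects pooled into error still receive an F value but
#' are flagged in the `pooled` column.
#'
#' @inheritParams yates_transform
#' @param pool_size Number of smallest mean squares pooled into the error term
#'   (default 2); must leave at least one unpooled effect.
#' @param rounding `"none"` (default) analyses the responses as given;
#'   `"integer"` first rounds them to the nearest integer (halves away from
#'   zero), the convention of hand-worked Yates tables.
#' @param f_critical Critical F value for [f_screen()].  Default `NULL` derives
#'   it as `qf(1 - alpha, 1, pool_size)`.
#' @param alpha Significance level used when `f_critical` is `NULL`
#'   (default 0.01).
#' @return A tibble of class `yates_table` with one row per run in standard
#'   order: `run`, `signs` (the run's signed level tuple), `term` (effect
#'   label, `"(1)"` for the base/total row), `response`, the k intermediate
#'   stage columns `stage_1` ... `stage_k`, `contrast`, `effect`,
#'   `mean_square`, `f_value` and `pooled`.  The base row has `NA` effect,
#'   mean square and F.  Attributes: `error_ms`, `error_df`, `pooled_terms`,
#'   `f_critical`, `k`.
#' @examples
#' acid <- c(7.14, 5.03, 22.61, 20.27, 10.00, 10.07, 36.23, 35.24)
#' yates_analysis(acid, rounding = "integer", f_critical = 98.49)
#' @export
yates_analysis <- function(responses, pool_size = 2L,
                           rounding = c("none", "integer"),
                           f_critical = NULL, alpha = 0.01) {
  rounding <- match.arg(rounding)
  y <- response_vector(responses)
  if (rounding == "integer") y <- round_half_away(y)

  stages <- yates_transform(y, keep_stages = TRUE)
  contrasts <- stages[, ncol(stages)]
  n <- length(y)
  k <- as.integer(round(log2(n)))
  n_effects <- n - 1L
  if (pool_size < 1L || pool_size > n_effects - 1L) {
    abort(sprintf("`pool_size` must be in 1..%d (leaving at least one unpooled effect).",
                  n_effects - 1L),
          class = "degopt_pooling_error")
  }

  effect <- c(NA_real_, contrasts[-1L] / 2^(k - 1L))
  ms <- c(NA_real_, contrasts[-1L]^2 / 2^k)
  pool_idx <- order(ms[-1L])[seq_len(pool_size)] + 1L
  error_ms <- mean(ms[pool_idx])
  error_df <- as.integer(pool_size)
  f_value <- ms / error_ms   # Inf if error_ms == 0 and ms > 0; NaN for 0/0
  if (is.null(f_critical)) f_critical <- qf(1 - alpha, 1, error_df)

  labels <- c("(1)", term_labels_standard(k)$labels)
  signs <- run_sign_labels(k)
  pooled <- seq_len(n) %in% pool_idx

  out <- tibble(
    run = seq_len(n), signs = signs, term = labels, response = y
  )
  stage_df <- as_tibble(as.data.frame(stages))
  names(stage_df) <- paste0("stage_", seq_len(k))
  out <- dplyr::bind_cols(out, stage_df)
  out$contrast <- contrasts
  out$effect <- effect
  out$mean_square <- ms
  out$f_value <- f_value
  out$pooled <- pooled

  structure(out,
            error_ms = error_ms, error_df = error_df,
            pooled_terms = labels[pool_idx],
            f_critical = f_critical, k = k,
            class = c("yates_table", class(out)))
}

run_sign_labels <- function(k) {
  n <- 2L^k
  vapply(seq_len(n) - 1L, function(i) {
    s <- ifelse(bitwAnd(i, 2L^(seq_len(k) - 1L)) > 0L, "+", "-")
    paste0("(", paste(s, collapse = ","), ")")
  }, character(1))
}

#' @export
print.yates_table <- function(x, ...) {
  cat(sprintf("<yates_table> 2^%d design; pooled error MS = %.4g on %d df (terms: %s)\n",
              attr(x, "k"), attr(x, "error_ms"), attr(x, "error_df"),
              paste(attr(x, "pooled_terms"), collapse = ", ")))
  NextMethod()
}

#' Screen significant effects against a critical F value
#'
#' Returns the labels of the effects whose pooled-error F value exceeds the
#' critical value, in standard term order.  Raising the critical value can
#' only shrink the significant set.
#'
#' @param table A [yates_analysis()] result.
#' @param f_critical Critical F.  Defaults to the value stored in the table
#'   (from its `alpha` or an explicit `f_critical` at construction).
#' @param main_effects_only If `TRUE`, only main-effect terms are screened.
#'   Screening reports in this field often discuss factors, not interactions;
#'   note that an interaction can clear the same F threshold (it does in the
#'   packaged acid data) and ignoring it is a judgment call, not arithmetic.
#' @return Character vector of significant effect labels.
#' @examples
#' acid <- c(7.14, 5.03, 22.61, 20.27, 10.00, 10.07, 36.23, 35.24)
#' f_screen(yates_analysis(acid, rounding = "integer"), f_critical = 98.49)
#' @export
f_screen <- function(table, f_critical = NULL, main_effects_only = FALSE) {
  stopifnot(inherits(table, "yates_table"))
  f_critical <- f_critical %||% attr(table, "f_critical")
  keep <- !is.na(table$f_value) & table$f_value > f_critical
  if (main_effects_only) {
    keep <- keep & !grepl("X.*X", table$term)
  }
  table$term[keep]
}

#' Pareto ranking of effects by normalized squares
#'
#' Ranks the non-intercept effects by their (signed, by default) effect value
#' and expresses each squared effect as a percentage of the total:
#' `normalized_square = 100 * E^2 / sum(E^2)`.  The normalized squares always
#' sum to 100; the leading rows of the ranking show which factors dominate
#' the response.
#'
#' @param table A [yates_analysis()] result.
#' @param sort `"signed"` (default) ranks by decreasing signed effect value,
#'   matching hand-worked Pareto tables; `"abs"` ranks by decreasing |E|,
#'   the usual convention for Pareto charts of standardized effects.
#' @return A tibble of class `pareto_ranking` with columns `rank`, `term`,
#'   `signs`, `effect`, `effect_squared` and `normalized_square`, plus a
#'   `total_effect_squared` attribute.
#' @examples
#' acid <- c(7.14, 5.03, 22.61, 20.27, 10.00, 10.07, 36.23, 35.24)
#' pareto_squares(yates_analysis(acid, rounding = "integer"))
#' @export
pareto_squares <- function(table, sort = c("signed", "abs")) {
  stopifnot(inherits(table, "yates_table"))
  sort <- match.arg(sort)
  eff <- table[!is.na(table$effect),
               c("term", "signs", "effect"), drop = FALSE]
  total <- sum(eff$effect^2)
  if (total <= 0) {
    abort("All effects are zero: normalized squares are undefined.",
          class = "degopt_undefined_normalization")
  }
  key <- if (sort == "signed") eff$effect else abs(eff$effect)
  eff <- eff[order(key, decreasing = TRUE), , drop = FALSE]
  out <- tibble(
    rank = seq_len(nrow(eff)),
    term = eff$term,
    signs = eff$signs,
    effect = eff$effect,
    effect_squared = eff$effect^2,
    normalized_square = 100 * eff$effect^2 / total
  )
  structure(out, total_effect_squared = total,
            class = c("pareto_ranking", class(out)))
}
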