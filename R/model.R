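#' Fit the saturated coded-unit factorial polynomial
#'
#' Fits `Y = b0 + sum_j b_j * (product of coded factors in term j)` over all
#' main effects and interactions of a 2^k design by the contrast formulas:
#' `b0 = sum(Y) / 2^k` and `b_term = sum(column * Y) / 2^k`, where `column` is
#' the coded (-1/+1) effect column.  Because the effect columns of a full
#' factorial are orthogonal, these are exactly the ordinary least squares
#' estimates, and the saturated model interpolates all 2^k observations.
#' Each coefficient is half the corresponding Yates effect.
#'
#' @param design An [fd_design()] object.
#' @param responses Responses aligned to the design's standard run order
#'   (anything accepted by [response_vector()]).
#' @param label Optional label (e.g. `"acid"`), carried into reports.
#' @return An object of class `fd_model`: list with `intercept`,
#'   `coefficients` (named by term label), `design`, `label`,
#'   `significant_terms` (`NULL` until set) and `r_squared_reduced`
#'   (`NULL` until [reduced_r_squared()] is applied).
#' @examples
#' acid_factors <- tibble::tibble(
#'   name = c("acid_strength", "temperature", "time"),
#'   low = c(0.01, 55, 30), high = c(0.10, 80, 60),
#'   units = c("mol/L", "degC", "min")
#' )
#' des <- fd_design(acid_factors)
#' fd_fit(des, c(7.14, 5.03, 22.61, 20.27, 10.00, 10.07, 36.23, 35.24))
#' @export
fd_fit <- function(design, responses, label = NULL) {
  y <- response_vector(responses)
  n <- design_runs(design)
  if (length(y) != n) {
    abort(sprintf("Design has %d runs but %d responses were given.", n, length(y)),
          class = "degopt_shape_error")
  }
  intercept <- sum(y) / n
  coefs <- as.numeric(crossprod(design$effect_matrix, y)) / n
  names(coefs) <- design$term_labels
  structure(
    list(intercept = intercept, coefficients = coefs,
         design = design, label = label,
         significant_terms = NULL, r_squared_reduced = NULL),
    class = "fd_model"
  )
}

#' @export
print.fd_model <- function(x, digits = 2, ...) {
  cat("<fd_model>", if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat(" ", model_equation(x, digits = digits), "\n")
  if (!is.null(x$significant_terms)) {
    cat("  significant terms:", paste(x$significant_terms, collapse = ", "), "\n")
  }
  if (!is.null(x$r_squared_reduced)) {
    cat(sprintf("  reduced-model R^2 = %.4f\n", x$r_squared_reduced))
  }
  invisible(x)
}

#' Render a fitted factorial polynomial as text
#' @param model An [fd_model()] object.
#' @param digits Decimal places for the printed coefficients (default 2,
#'   matching how such equations are usually reported).
#' @return A single string like `"Y = 18.32 - 0.67 X1 + 10.26 X2 + ..."`.
#' @export
model_equation <- function(model, digits = 2) {
  b <- round(model$coefficients, digits)
  terms <- sprintf("%s %s %s", ifelse(b < 0, "-", "+"),
                   format(abs(b), trim = TRUE), names(b))
  paste("Y =", format(round(model$intercept, digits)), paste(terms, collapse = " "))
}

#' @export
coef.fd_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict the factorial polynomial at coded points
#'
#' @param object An [fd_model()] object.
#' @param newdata A numeric vector of length k (one coded point), a matrix or
#'   data frame with k columns (one row per point), or `NULL` for the design
#'   points.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (% degradation).
#' @export
predict.fd_model <- function(object, newdata = NULL, ...) {
  des <- object$design
  k <- design_k(des)
  if (is.null(newdata)) {
    pts <- as.matrix(des$runs[, -1L, drop = FALSE])
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(newdata) != k) {
      abort(sprintf("Expected a coded point of length %d.", k),
            class = "degopt_shape_error")
    }
    pts <- matrix(newdata, nrow = 1L)
  } else {
    pts <- as.matrix(as.data.frame(newdata))
    if (ncol(pts) != k) {
      abort(sprintf("Expected %d coded columns, got %d.", k, ncol(pts)),
            class = "degopt_shape_error")
    }
  }
  term_vals <- vapply(des$term_members, function(idx) {
    apply(pts[, idx, drop = FALSE], 1L, prod)
  }, numeric(nrow(pts)))
  if (nrow(pts) == 1L) term_vals <- matrix(term_vals, nrow = 1L)
  as.numeric(object$intercept + term_vals %*% object$coefficients)
}

#' @export
tidy.fd_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    effect = c(NA_real_, 2 * unname(x$coefficients))
  )
}

#' @export
glance.fd_model <- function(x, ...) {
  tibble(
    n_runs = design_runs(x$design),
    n_factors = design_k(x$design),
    r_squared_reduced = x$r_squared_reduced %||% NA_real_,
    n_significant = length(x$significant_terms %||% character())
  )
}

#' Reduced-model R-squared from a Yates table
#'
#' The share of the effect variation captured by a chosen subset of terms:
#' `R^2 = sum(MS of the chosen terms) / sum(MS of all non-intercept terms)`.
#' Since every effect has one degree of freedom, this equals the classical
#' R-squared of the reduced model refit to the design points.  The
#' significant set is an explicit argument and is never inferred silently.
#'
#' @param table A [yates_analysis()] result.
#' @param significant_terms Character vector of term labels to keep.
#' @return The reduced-model R^2 in \[0, 1\].
#' @examples
#' acid <- c(7, 5, 23, 20, 10, 10, 36, 35)
#' reduced_r_squared(yates_analysis(acid), c("X2", "X3"))  # 0.9462
#' @export
reduced_r_squared <- function(table, significant_terms) {
  stopifnot(inherits(table, "yates_table"))
  if (length(significant_terms) == 0L) {
    abort("At least one term is required for a reduced model.",
          class = "degopt_undefined_error")
  }
  terms <- table$term[!is.na(table$mean_square)]
  unknown <- setdiff(significant_terms, terms)
  if (length(unknown)) {
    abort(paste0("Unknown term(s): ", paste(unknown, collapse = ", ")),
          class = "degopt_shape_error")
  }
  ms <- table$mean_square[!is.na(table$mean_square)]
  names(ms) <- terms
  sum(ms[significant_terms]) / sum(ms)
}

#' Attach a significant-term set (and its reduced R-squared) to a model
#'
#' @param model An [fd_model()] object.
#' @param table The [yates_analysis()] table the screening came from.
#' @param significant_terms Character vector of term labels.
#' @return The model, with `significant_terms` and `r_squared_reduced` set.
#' @export
set_significant_terms <- function(model, table, significant_terms) {
  stopifnot(inherits(model, "fd_model"))
  model$significant_terms <- significant_terms
  model$r_squared_reduced <- reduced_r_squared(table, significant_terms)
  model
}
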