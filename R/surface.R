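#' Coefficients used for surface arithmetic, optionally paper-rounded
#'
#' Response-surface tables in method-development reports are typically
#' computed from the 2-dp rounded published equation rather than from the
#' full-precision fit.  `rounding = "2dp"` reproduces that arithmetic;
#' `"full"` (default) uses the fitted coefficients as they are.
#' @noRd
surface_coefs <- function(model, rounding = c("full", "2dp"), digits = 2) {
  rounding <- match.arg(rounding)
  b0 <- model$intercept
  b <- model$coefficients
  if (rounding == "2dp") {
    b0 <- round(b0, digits)
    b <- round(b, digits)
  }
  list(intercept = b0, coefficients = b)
}

# Resolve a factor identifier ("X2", factor name, or index) to its position.
factor_index <- function(design, id) {
  k <- design_k(design)
  if (is.numeric(id)) {
    id <- as.integer(id)
    if (id < 1L || id > k) {
      abort(sprintf("Factor index %d out of range 1..%d.", id, k),
            class = "degopt_shape_error")
    }
    return(id)
  }
  xlab <- paste0("X", seq_len(k))
  hit <- match(id, xlab)
  if (is.na(hit)) hit <- match(id, design$factors$name)
  if (is.na(hit)) {
    abort(sprintf("Unknown factor '%s' (use X1..X%d or a factor name).", id, k),
          class = "degopt_shape_error")
  }
  hit
}

#' Solve the fitted polynomial for one factor at a target response
#'
#' With every other factor fixed at a coded value, the factorial polynomial is
#' linear in the remaining factor, so the coded level that attains a target %
#' degradation is obtained in closed form:
#' `x = (target - constant part) / (linear coefficient after substitution)`.
#'
#' @param model An [fd_model()] object.
#' @param target Target response (% degradation).
#' @param solve Factor to solve for: `"Xj"` label, factor name, or index.
#' @param fixed Named vector/list of coded values for every other factor
#'   (names as `"Xj"` or factor names).
#' @param rounding `"full"` (default) uses full-precision coefficients;
#'   `"2dp"` uses the 2-dp rounded equation, the arithmetic that published
#'   surface tables are computed with.
#' @return The solved coded value.  Errors with class `degopt_no_solution` if
#'   the effective linear coefficient is (numerically) zero.
#' @examples
#' acid_factors <- tibble::tibble(
#'   name = c("acid_strength", "temperature", "time"),
#'   low = c(0.01, 55, 30), high = c(0.10, 80, 60)
#' )
#' mod <- fd_fit(fd_design(acid_factors),
#'               c(7.14, 5.03, 22.61, 20.27, 10.00, 10.07, 36.23, 35.24))
#' invert_single_factor(mod, 10, solve = "X3", fixed = c(X1 = 0, X2 = -1),
#'                      rounding = "2dp")  # 0.98
#' @export
invert_single_factor <- function(model, target, solve, fixed = NULL,
                                 rounding = c("full", "2dp")) {
  des <- model$design
  k <- design_k(des)
  s_idx <- factor_index(des, solve)
  fx <- resolve_fixed(des, fixed, exclude = s_idx)
  others <- setdiff(seq_len(k), s_idx)
  if (!all(others %in% fx$idx)) {
    missing <- setdiff(others, fx$idx)
    abort(paste0("Fix a coded value for every non-solved factor; missing: ",
                 paste0("X", missing, collapse = ", ")),
          class = "degopt_shape_error")
  }
  cf <- surface_coefs(model, rounding)

  const <- cf$intercept
  lin <- 0
  fixed_vals <- setNames(rep(NA_real_, k), seq_len(k))
  fixed_vals[as.character(fx$idx)] <- fx$values
  for (t in seq_along(des$term_members)) {
    idx <- des$term_members[[t]]
    b <- cf$coefficients[[t]]
    if (s_idx %in% idx) {
      lin <- lin + b * prod(fixed_vals[as.character(setdiff(idx, s_idx))])
    } else {
      const <- const + b * prod(fixed_vals[as.character(idx)])
    }
  }
  if (abs(lin) < 1e-12) {
    abort("The polynomial has no dependence on the solved factor at these fixed values.",
          class = "degopt_no_solution")
  }
  (target - const) / lin
}

resolve_fixed <- function(design, fixed, exclude = integer()) {
  if (is.null(fixed) || length(fixed) == 0L) {
    return(list(idx = integer(), values = numeric()))
  }
  fixed <- unlist(fixed)
  if (is.null(names(fixed)) || any(!nzchar(names(fixed)))) {
    abort("`fixed` must be a named vector of coded values.",
          class = "degopt_shape_error")
  }
  idx <- vapply(names(fixed), factor_index, integer(1), design = design)
  if (anyDuplicated(idx)) {
    abort("Duplicate factors in `fixed`.", class = "degopt_shape_error")
  }
  if (any(idx %in% exclude)) {
    abort("`fixed` must not include the solved factor.",
          class = "degopt_shape_error")
  }
  list(idx = unname(idx), values = as.numeric(fixed))
}

#' Tabulate a response-surface slice
#'
#' Solves for one factor at each combination of a grid factor's coded levels
#' and a set of target responses, with any remaining factors held fixed
#' (default 0, the design midpoint).  Solutions outside the \[-1, +1\]
#' experimental domain are retained and marked, not clipped — they show where
#' a target is unattainable within the studied conditions.
#'
#' @inheritParams invert_single_factor
#' @param grid_factor Factor whose coded levels index the rows.
#' @param grid_levels Coded levels of `grid_factor` (e.g. `seq(-1, 1, 0.5)`).
#' @param targets Target responses (%), one column per target.
#' @param fixed Coded values for factors other than `solve` and `grid_factor`
#'   (default: all 0).
#' @return A tibble of class `surface_slice`, long format: `grid_value`,
#'   `target`, `solved` (coded), `in_domain`.  Each solved value satisfies the
#'   model equation at its point to 1e-6 (checked at construction).
#'   Use [tidyr::pivot_wider()] for the classic rows-by-targets layout.
#' @export
surface_table <- function(model, solve, grid_factor, grid_levels, targets,
                          fixed = NULL, rounding = c("full", "2dp")) {
  rounding <- match.arg(rounding)
  des <- model$design
  k <- design_k(des)
  s_idx <- factor_index(des, solve)
  g_idx <- factor_index(des, grid_factor)
  if (s_idx == g_idx) {
    abort("`solve` and `grid_factor` must differ.", class = "degopt_shape_error")
  }
  fx <- resolve_fixed(des, fixed, exclude = c(s_idx, g_idx))
  rest <- setdiff(seq_len(k), c(s_idx, g_idx, fx$idx))
  fx_idx <- c(fx$idx, rest)
  fx_val <- c(fx$values, rep(0, length(rest)))

  grid <- tidyr::expand_grid(grid_value = grid_levels, target = targets)
  if (nrow(grid) == 0L) {
    out <- tibble(grid_value = numeric(), target = numeric(),
                  solved = numeric(), in_domain = logical())
    return(structure(out, solve = s_idx, grid_factor = g_idx,
                     class = c("surface_slice", class(out))))
  }
  solved <- purrr::pmap_dbl(grid, function(grid_value, target) {
    fixed_all <- setNames(c(grid_value, fx_val), paste0("X", c(g_idx, fx_idx)))
    invert_single_factor(model, target, solve = s_idx, fixed = fixed_all,
                         rounding = rounding)
  })

  # substitution check against the same coefficient set used to solve
  cf <- surface_coefs(model, rounding)
  check_model <- model
  check_model$intercept <- cf$intercept
  check_model$coefficients <- cf$coefficients
  pts <- matrix(0, nrow(grid), k)
  pts[, g_idx] <- grid$grid_value
  pts[, s_idx] <- solved
  if (length(fx_idx)) pts[, fx_idx] <- matrix(fx_val, nrow(grid), length(fx_idx), byrow = TRUE)
  resid <- predict(check_model, pts) - grid$target
  if (any(abs(resid) > 1e-6)) {
    abort("Internal error: solved surface point fails the substitution check.",
          class = "degopt_internal_error")
  }

  out <- dplyr::mutate(grid, solved = solved,
                       in_domain = abs(solved) <= 1 + 1e-9)
  structure(out, solve = s_idx, grid_factor = g_idx, rounding = rounding,
            class = c("surface_slice", class(out)))
}

#' Choose an in-domain condition that attains a target response
#'
#' Finds a coded point inside the \[-1, +1\]^k experimental domain whose
#' predicted response equals the target, then decodes it to actual units.
#' Default strategy: factors named in `fix` (or, if `fix` is `NULL`, factors
#' not among the model's significant terms) are held at 0; each remaining
#' factor except the solved one is tried at the domain bounds (and 0); the
#' solved factor is obtained by [invert_single_factor()].  Among feasible
#' candidates the point with the smallest maximum |coded value| wins, ties
#' broken lexicographically in factor order.
#'
#' Since a multilinear polynomial attains its extrema at the corners of the
#' domain, achievability of the target is checked by corner enumeration
#' before solving; an unattainable target raises `degopt_domain_error`
#' reporting the achievable range.
#'
#' @inheritParams invert_single_factor
#' @param solve Factor solved in closed form.  Default: the last significant
#'   main-effect factor (or the last factor if no significant set is stored).
#' @param fix Named coded values for factors to hold fixed (default: 0 for
#'   every factor not appearing in the model's significant terms).
#' @return An object of class `fd_condition`: list with `coded` and `actual`
#'   named points, `predicted` (the target, by construction), `in_domain`
#'   (always `TRUE` on success) and `target`.
#' @examples
#' acid_factors <- tibble::tibble(
#'   name = c("acid_strength", "temperature", "time"),
#'   low = c(0.01, 55, 30), high = c(0.10, 80, 60)
#' )
#' mod <- fd_fit(fd_design(acid_factors),
#'               c(7.14, 5.03, 22.61, 20.27, 10.00, 10.07, 36.23, 35.24))
#' mod$significant_terms <- c("X2", "X3")
#' choose_condition(mod, target = 10)
#' @export
choose_condition <- function(model, target, solve = NULL, fix = NULL,
                             rounding = c("full", "2dp")) {
  rounding <- match.arg(rounding)
  des <- model$design
  k <- design_k(des)
  cf <- surface_coefs(model, rounding)
  eval_model <- model
  eval_model$intercept <- cf$intercept
  eval_model$coefficients <- cf$coefficients

  corners <- as.matrix(des$runs[, -1L, drop = FALSE])
  rng <- range(predict(eval_model, corners))
  if (target < rng[1] - 1e-9 || target > rng[2] + 1e-9) {
    abort(sprintf("Target %.4g%% is outside the achievable range [%.4g, %.4g]%% over the experimental domain.",
                  target, rng[1], rng[2]),
          class = "degopt_domain_error")
  }

  # which factors are free to move: those in the significant set, unless the
  # caller fixed things explicitly
  sig_factors <- significant_factor_indices(des, model$significant_terms)
  if (is.null(fix)) {
    fixed0 <- setdiff(seq_len(k), sig_factors)
    fix_idx <- fixed0
    fix_val <- rep(0, length(fixed0))
  } else {
    fx <- resolve_fixed(des, fix)
    fix_idx <- fx$idx
    fix_val <- fx$values
  }
  free <- setdiff(seq_len(k), fix_idx)
  if (length(free) == 0L) {
    abort("All factors are fixed; nothing to solve for.", class = "degopt_shape_error")
  }
  s_idx <- if (is.null(solve)) free[length(free)] else factor_index(des, solve)
  if (!s_idx %in% free) {
    abort("The solved factor must not be fixed.", class = "degopt_shape_error")
  }
  search <- setdiff(free, s_idx)

  cand_levels <- rep(list(c(-1, 0, 1)), length(search))
  cand <- if (length(search)) expand.grid(cand_levels) else data.frame(row.names = 1)
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    point <- setNames(rep(NA_real_, k), paste0("X", seq_len(k)))
    point[fix_idx] <- fix_val
    if (length(search)) point[search] <- as.numeric(cand[i, ])
    fixed_all <- point[-s_idx]
    names(fixed_all) <- paste0("X", setdiff(seq_len(k), s_idx))
    sol <- tryCatch(
      invert_single_factor(model, target, solve = s_idx, fixed = fixed_all,
                           rounding = rounding),
      degopt_no_solution = function(e) NA_real_
    )
    if (is.na(sol) || abs(sol) > 1 + 1e-9) next
    point[s_idx] <- sol
    cand_point <- unname(point)
    key <- max(abs(cand_point))
    if (is.null(best) || key < best$key - 1e-12 ||
        (abs(key - best$key) <= 1e-12 && lex_less(cand_point, best$point))) {
      best <- list(point = cand_point, key = key)
    }
  }
  if (is.null(best)) {
    abort("No in-domain coded point attains the target with this strategy; try freeing more factors.",
          class = "degopt_domain_error")
  }

  coded <- setNames(best$point, des$factors$name)
  actual <- decode_point(des, coded, warn_extrapolation = FALSE)
  predicted <- predict(eval_model, unname(coded))
  structure(
    list(coded = coded, actual = actual, units = des$factors$units,
         predicted = predicted, target = target,
         in_domain = all(abs(coded) <= 1 + 1e-9), rounding = rounding),
    class = "fd_condition"
  )
}

significant_factor_indices <- function(design, significant_terms) {
  k <- design_k(design)
  if (is.null(significant_terms) || length(significant_terms) == 0L) {
    return(seq_len(k))
  }
  pos <- match(significant_terms, design$term_labels)
  if (anyNA(pos)) {
    abort("Significant terms do not match the design's term labels.",
          class = "degopt_shape_error")
  }
  sort(unique(unlist(design$term_members[pos])))
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' @export
print.fd_condition <- function(x, ...) {
  cat(sprintf("<fd_condition> target %.4g%% degradation (predicted %.6g%%)\n",
              x$target, x$predicted))
  df <- data.frame(factor = names(x$coded), coded = round(unname(x$coded), 4),
                   actual = signif(unname(x$actual), 6), units = x$units)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare predicted and observed responses at a chosen condition
#'
#' One-sample comparison of confirmation-run responses against the predicted
#' response: mean observed, difference, and a one-sample t test (when at least
#' two replicates with nonzero spread are available).
#'
#' @param condition An [choose_condition()] result, or a single predicted
#'   value (%).
#' @param observed Numeric vector of observed % degradation replicates.
#' @param conf_level Confidence level for the t interval (default 0.95).
#' @return A one-row tibble: `predicted`, `mean_observed`, `difference`,
#'   `n`, `t_statistic`, `df`, `p_value` (`NA` with zero spread; a zero-spread
#'   set equal to the prediction is reported as no difference).
#' @export
compare_predicted_observed <- function(condition, observed, conf_level = 0.95) {
  predicted <- if (inherits(condition, "fd_condition")) condition$predicted else as.numeric(condition)
  if (length(observed) == 0L || anyNA(observed)) {
    abort("`observed` must be a non-empty numeric vector without NAs.",
          class = "degopt_input_error")
  }
  m <- mean(observed)
  s <- if (length(observed) > 1L) sd(observed) else NA_real_
  if (length(observed) >= 2L && isTRUE(s > 0)) {
    tt <- t.test(observed, mu = predicted, conf.level = conf_level)
    tstat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else {
    tstat <- NA_real_; df <- NA_real_
    p <- if (isTRUE(all.equal(m, predicted))) 1 else NA_real_
  }
  tibble(predicted = predicted, mean_observed = m, difference = m - predicted,
         n = length(observed), t_statistic = tstat, df = df, p_value = p)
}
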