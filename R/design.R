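#' Build a two-level full factorial design in standard (Yates) order
#'
#' Constructs the 2^k coded run matrix for k two-level factors, together with
#' every interaction column.  Runs are ordered in standard (Yates) order: the
#' first listed factor alternates fastest (-1, +1, -1, +1, ...), the second
#' factor alternates in blocks of two, and so on.  This ordering is a
#' prerequisite for the Yates algorithm used by [yates_analysis()].
#'
#' @param factors A data frame with one row per factor and columns
#'   `name` (unique, non-empty label), `low` and `high` (actual factor levels,
#'   `high > low`) and optionally `units` (free-text unit label).
#'
#' @return An object of class `fd_design`: a list with
#'   \describe{
#'     \item{factors}{the validated factor tibble,}
#'     \item{runs}{a tibble with a `run` column and one coded (-1/+1) column
#'       per factor, 2^k rows,}
#'     \item{term_labels}{labels of the 2^k - 1 effect columns, main effects
#'       then interactions, in standard order (e.g. `"X1"`, `"X2"`, `"X1X2"`,
#'       `"X3"`, ...), named by the factors they involve,}
#'     \item{effect_matrix}{the 2^k x (2^k - 1) matrix of effect columns
#'       (main-effect columns and their elementwise products).}
#'   }
#'
#' @details All effect columns of a full factorial are mutually orthogonal and
#' orthogonal to the intercept column, so the full model matrix `M` (intercept
#' plus effects) satisfies `t(M) %*% M == 2^k * I`.  This orthogonality is what
#' makes the contrast formulas used by [fd_fit()] equal to least squares.
#'
#' @examples
#' acid_factors <- tibble::tibble(
#'   name  = c("acid_strength", "temperature", "time"),
#'   low   = c(0.01, 55, 30),
#'   high  = c(0.10, 80, 60),
#'   units = c("mol/L", "degC", "min")
#' )
#' fd_design(acid_factors)
#' @export
fd_design <- function(factors) {
  factors <- validate_factor_table(factors)
  k <- nrow(factors)
  if (k > 12) {
    abort("A full factorial with more than 12 factors (>4096 runs) is not supported.",
          class = "degopt_invalid_design")
  }

  n <- 2L^k
  # first factor alternates fastest
  main <- vapply(seq_len(k), function(j) {
    rep(rep(c(-1, 1), each = 2L^(j - 1L)), length.out = n)
  }, numeric(n))
  colnames(main) <- factors$name

  tl <- term_labels_standard(k)
  eff <- vapply(tl$members, function(idx) {
    apply(main[, idx, drop = FALSE], 1L, prod)
  }, numeric(n))
  colnames(eff) <- tl$labels

  runs <- as_tibble(as.data.frame(main))
  runs <- dplyr::bind_cols(tibble(run = seq_len(n)), runs)

  structure(
    list(factors = factors, runs = runs,
         term_labels = tl$labels, term_members = tl$members,
         effect_matrix = eff),
    class = "fd_design"
  )
}

# Standard-order effect labels: subsets of factors ordered so that the subset
# containing factor j appears as soon as run index 2^(j-1) is reached, i.e.
# (1), X1, X2, X1X2, X3, X1X3, X2X3, X1X2X3 for k = 3 (intercept omitted).
term_labels_standard <- function(k) {
  subsets <- lapply(seq_len(2L^k - 1L), function(m) {
    which(bitwAnd(m, 2L^(seq_len(k) - 1L)) > 0L)
  })
  labels <- vapply(subsets, function(idx) paste0("X", idx, collapse = ""), character(1))
  list(labels = labels, members = subsets)
}

validate_factor_table <- function(factors) {
  if (!is.data.frame(factors)) {
    abort("`factors` must be a data frame with columns name, low, high.",
          class = "degopt_invalid_design")
  }
  required <- c("name", "low", "high")
  missing <- setdiff(required, names(factors))
  if (length(missing)) {
    abort(paste0("`factors` is missing column(s): ", paste(missing, collapse = ", ")),
          class = "degopt_invalid_design")
  }
  if (nrow(factors) < 1L) {
    abort("At least one factor is required.", class = "degopt_invalid_design")
  }
  factors <- as_tibble(factors)
  if (!"units" %in% names(factors)) factors$units <- ""
  factors$name <- as.character(factors$name)
  if (any(!nzchar(factors$name)) || anyNA(factors$name)) {
    abort("Factor names must be non-empty.", class = "degopt_invalid_design")
  }
  if (anyDuplicated(factors$name)) {
    abort("Factor names must be unique within a design.", class = "degopt_invalid_design")
  }
  if (!is.numeric(factors$low) || !is.numeric(factors$high) ||
      anyNA(factors$low) || anyNA(factors$high)) {
    abort("Factor levels `low` and `high` must be finite numbers.",
          class = "degopt_invalid_design")
  }
  bad <- factors$high <= factors$low
  if (any(bad)) {
    abort(paste0("`high` must exceed `low` for factor(s): ",
                 paste(factors$name[bad], collapse = ", ")),
          class = "degopt_invalid_spec")
  }
  factors[, c("name", "low", "high", "units")]
}

#' @export
print.fd_design <- function(x, ...) {
  k <- nrow(x$factors)
  cat(sprintf("<fd_design> 2^%d full factorial, %d runs (standard order)\n", k, 2L^k))
  cat("Factors:\n")
  print(as.data.frame(x$factors), row.names = FALSE)
  cat("Effect terms:", paste(x$term_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of runs and factors of a design
#' @param design An [fd_design()] object.
#' @return Integer number of runs (`design_runs`) or factors (`design_k`).
#' @keywords internal
#' @export
design_runs <- function(design) nrow(design$runs)

#' @rdname design_runs
#' @export
design_k <- function(design) nrow(design$factors)

#' Convert between actual and coded factor units
#'
#' Coded units place the low level at -1 and the high level at +1:
#' `coded = (actual - midpoint) / half_range`.  `decode_values()` is the exact
#' inverse: `actual = midpoint + coded * half_range`.
#'
#' Values outside the \[-1, +1\] experimental domain are accepted (the
#' transformation is affine everywhere) but a warning of class
#' `degopt_extrapolation` is emitted, because conclusions from a two-level
#' design only hold inside the domain spanned by the levels.
#'
#' @param actual,coded Numeric vectors of values to transform.
#' @param low,high The actual low (-1) and high (+1) levels; `high > low`.
#' @param warn_extrapolation Emit a warning when a coded value (input or
#'   output) falls outside \[-1, +1\]?  Default `TRUE`.
#' @return A numeric vector of the same length.
#' @examples
#' code_values(67.5, low = 55, high = 80)   # 0 at the midpoint
#' decode_values(-0.86, low = 55, high = 80) # 56.75
#' @export
code_values <- function(actual, low, high, warn_extrapolation = TRUE) {
  check_levels(low, high)
  coded <- (actual - (low + high) / 2) / ((high - low) / 2)
  if (warn_extrapolation && any(is.finite(coded) & abs(coded) > 1 + 1e-12)) {
    warn("Coded value(s) outside the [-1, +1] experimental domain (extrapolation).",
         class = "degopt_extrapolation")
  }
  coded
}

#' @rdname code_values
#' @export
decode_values <- function(coded, low, high, warn_extrapolation = TRUE) {
  check_levels(low, high)
  if (warn_extrapolation && any(is.finite(coded) & abs(coded) > 1 + 1e-12)) {
    warn("Coded value(s) outside the [-1, +1] experimental domain (extrapolation).",
         class = "degopt_extrapolation")
  }
  (low + high) / 2 + coded * ((high - low) / 2)
}

check_levels <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || anyNA(low) || anyNA(high)) {
    abort("Levels must be finite numbers.", class = "degopt_invalid_spec")
  }
  if (any(high <= low)) {
    abort("Degenerate factor levels: `high` must exceed `low`.",
          class = "degopt_invalid_spec")
  }
  invisible(NULL)
}

#' Code or decode a whole design point
#'
#' Applies [code_values()] / [decode_values()] factor by factor using the
#' levels stored in a design.
#'
#' @param design An [fd_design()] object.
#' @param point Numeric vector of length k, in factor order (names, if
#'   present, must match the design's factor names).
#' @inheritParams code_values
#' @return A named numeric vector of length k.
#' @export
code_point <- function(design, point, warn_extrapolation = TRUE) {
  point <- check_point(design, point)
  out <- code_values(point, design$factors$low, design$factors$high,
                     warn_extrapolation = warn_extrapolation)
  setNames(out, design$factors$name)
}

#' @rdname code_point
#' @export
decode_point <- function(design, point, warn_extrapolation = TRUE) {
  point <- check_point(design, point)
  out <- decode_values(point, design$factors$low, design$factors$high,
                       warn_extrapolation = warn_extrapolation)
  setNames(out, design$factors$name)
}

check_point <- function(design, point) {
  k <- design_k(design)
  if (length(point) != k) {
    abort(sprintf("Expected a point of length %d (one value per factor), got %d.",
                  k, length(point)),
          class = "degopt_shape_error")
  }
  if (!is.null(names(point)) && all(nzchar(names(point)))) {
    missing <- setdiff(design$factors$name, names(point))
    if (length(missing)) {
      abort(paste0("Point is missing factor(s): ", paste(missing, collapse = ", ")),
            class = "degopt_shape_error")
    }
    point <- point[design$factors$name]
  }
  as.numeric(point)
}

#' Write a coded design to CSV
#'
#' Writes the run matrix plus all interaction columns with -1/1 integer signs,
#' matching the layout of a printed experimental matrix.
#'
#' @param design An [fd_design()] object.
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  main <- design$runs
  names(main)[-1] <- design$factors$name
  inter <- lengths(design$term_members) > 1L
  out <- dplyr::bind_cols(
    main,
    as_tibble(as.data.frame(design$effect_matrix[, inter, drop = FALSE]))
  )
  out <- dplyr::mutate(out, dplyr::across(-"run", as.integer))
  readr::write_csv(out, path)
  invisible(path)
}
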