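#' Percent degradation from peak areas
#'
#' The response of a forced-degradation run is the relative loss of the drug
#' peak: `100 * (area_unstressed - area_stressed) / area_unstressed`.  A single
#' unstressed reference chromatogram at the same nominal concentration serves
#' as the comparator for a whole response set.
#'
#' @param area_unstressed Peak area of the unstressed reference (> 0).
#' @param area_stressed Peak area after stress (>= 0).  May be vectorised
#'   against a scalar reference.
#' @return Percent degradation.  A stressed area larger than the reference
#'   gives a negative value and a warning of class `degopt_negative_degradation`
#'   (apparent gain, usually an integration or dilution problem).
#' @examples
#' percent_degradation(1000, 900)  # 10
#' @export
percent_degradation <- function(area_unstressed, area_stressed) {
  if (!is.numeric(area_unstressed) || anyNA(area_unstressed) ||
      any(area_unstressed <= 0)) {
    abort("`area_unstressed` must be > 0.", class = "degopt_domain_error")
  }
  if (!is.numeric(area_stressed) || anyNA(area_stressed) || any(area_stressed < 0)) {
    abort("`area_stressed` must be >= 0.", class = "degopt_domain_error")
  }
  out <- 100 * (area_unstressed - area_stressed) / area_unstressed
  if (any(out < 0)) {
    warn("Stressed area exceeds unstressed reference: negative % degradation.",
         class = "degopt_negative_degradation")
  }
  out
}

#' Assemble a response vector aligned to a factorial design
#'
#' Takes per-run degradation records and returns the % degradation responses in
#' the design's standard run order, ready for [yates_analysis()] and
#' [fd_fit()].  Each record either states `response_pct` directly or provides
#' the pair `area_unstressed`/`area_stressed` from which it is computed via
#' [percent_degradation()] — never both.
#'
#' @param records A data frame with a `run` column (1 .. 2^k, each exactly
#'   once, any order) and either `response_pct` or both `area_unstressed` and
#'   `area_stressed`.  Rows may mix the two forms.
#' @param design An [fd_design()] object.
#' @param label Optional label for the response set (e.g. `"acid"`).
#' @return A tibble of class `fd_responses` with columns `run` and `response`
#'   in standard order, carrying the label as an attribute.
#' @export
assemble_responses <- function(records, design, label = NULL) {
  if (!is.data.frame(records) || !"run" %in% names(records)) {
    abort("`records` must be a data frame with a `run` column.",
          class = "degopt_alignment_error")
  }
  n <- design_runs(design)
  run <- as.integer(records$run)
  if (anyNA(run) || length(run) != n || !setequal(run, seq_len(n)) ||
      anyDuplicated(run)) {
    abort(sprintf("Expected exactly one record per run 1..%d; got runs {%s}.",
                  n, paste(sort(run), collapse = ", ")),
          class = "degopt_alignment_error")
  }

  has_direct <- "response_pct" %in% names(records)
  has_areas <- all(c("area_unstressed", "area_stressed") %in% names(records))
  if (!has_direct && !has_areas) {
    abort("`records` needs `response_pct` or `area_unstressed`+`area_stressed`.",
          class = "degopt_alignment_error")
  }

  direct <- if (has_direct) records$response_pct else rep(NA_real_, n)
  a_un <- if (has_areas) records$area_unstressed else rep(NA_real_, n)
  a_st <- if (has_areas) records$area_stressed else rep(NA_real_, n)

  both <- !is.na(direct) & (!is.na(a_un) | !is.na(a_st))
  if (any(both)) {
    abort(sprintf("Run(s) %s give both a direct response and peak areas; provide one.",
                  paste(run[both], collapse = ", ")),
          class = "degopt_ambiguity_error")
  }
  value <- direct
  from_areas <- is.na(direct)
  if (any(from_areas)) {
    if (any(is.na(a_un[from_areas])) || any(is.na(a_st[from_areas]))) {
      abort("Records without `response_pct` must provide both peak areas.",
            class = "degopt_alignment_error")
    }
    value[from_areas] <- percent_degradation(a_un[from_areas], a_st[from_areas])
  }
  if (any(!is.finite(value))) {
    abort("All responses must be finite.", class = "degopt_alignment_error")
  }

  out <- tibble(run = run, response = value)
  out <- dplyr::arrange(out, .data$run)
  structure(out, label = label, class = c("fd_responses", class(out)))
}

#' Extract a plain response vector
#'
#' Accepts an `fd_responses` tibble, a data frame with a `response` column, or
#' a bare numeric vector, and returns the numeric responses in run order.
#' @param responses Responses in any of the accepted forms.
#' @return Numeric vector.
#' @keywords internal
#' @export
response_vector <- function(responses) {
  if (is.data.frame(responses)) {
    if (!"response" %in% names(responses)) {
      abort("Response data frame must have a `response` column.",
            class = "degopt_shape_error")
    }
    if ("run" %in% names(responses)) {
      responses <- responses[order(responses$run), , drop = FALSE]
    }
    return(as.numeric(responses$response))
  }
  if (!is.numeric(responses)) {
    abort("Responses must be numeric or a data frame with a `response` column.",
          class = "degopt_shape_error")
  }
  as.numeric(responses)
}
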