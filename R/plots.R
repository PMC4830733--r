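#' Pareto chart of normalized effect squares
#'
#' Bar chart of each ranked effect's normalized square (% of the total
#' squared effect), the standard visual for factor screening.
#'
#' @param object A [pareto_squares()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pareto_ranking <- function(object, ...) {
  dat <- dplyr::mutate(as_tibble(object),
                       term = factor(.data$term, levels = .data$term))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$term, y = .data$normalized_square)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Effect", y = "Normalized square (% of ΣE²)",
                  title = "Pareto chart of factorial effects") +
    ggplot2::theme_minimal()
}

#' Response-surface slice plot
#'
#' Solved coded levels of the inverted factor versus the grid factor, one
#' line per target response.  The shaded band marks the \[-1, +1\]
#' experimental domain; points outside it are extrapolations.
#'
#' @param object A [surface_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surface_slice <- function(object, ...) {
  dat <- dplyr::mutate(as_tibble(object), target = factor(.data$target))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$grid_value, y = .data$solved,
                                    colour = .data$target, group = .data$target)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = -1, ymax = 1,
                      alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_domain)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = sprintf("X%d (coded)", attr(object, "grid_factor")),
                  y = sprintf("Solved X%d (coded)", attr(object, "solve")),
                  colour = "Target (%)", shape = "In domain") +
    ggplot2::theme_minimal()
}

#' Calibration-curve plot
#'
#' Raw points with the fitted least-squares line.
#'
#' @param object A [fit_calibration()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$peak_area)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Concentration", y = "Peak area",
                  title = sprintf("y = %.5g x %+.5g (r = %.4f)",
                                  object$slope, object$intercept,
                                  object$correlation)) +
    ggplot2::theme_minimal()
}

#' Observed responses against the fitted factorial polynomial
#'
#' For a saturated fit the points sit exactly on the identity line; the plot
#' is mainly useful for reduced or synthetic-data fits.
#'
#' @param object An [fd_fit()] result.
#' @param responses Optional observed responses (default: the design points'
#'   saturated predictions, i.e. the fit's own interpolation).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fd_model <- function(object, responses = NULL, ...) {
  pred <- predict(object)
  obs <- if (is.null(responses)) pred else response_vector(responses)
  dat <- tibble(predicted = pred, observed = obs)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted % degradation", y = "Observed % degradation") +
    ggplot2::theme_minimal()
}
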