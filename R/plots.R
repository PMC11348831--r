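#' Plot a relaxation trace
#'
#' Vertex count, edge count and mean edge length against the Lloyd iteration
#' index: the classical picture of a structure settling into a centroidal
#' Voronoi tessellation.
#'
#' @param object A [relaxation_trace][relax()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relaxation_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$records[, c("iteration", "V", "E", "epsilon")],
    cols = c("V", "E", "epsilon"), names_to = "parameter",
    values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Lloyd iteration", y = NULL,
                  title = "Structural parameters along Lloyd relaxation")
}

#' Plot an ensemble table
#'
#' Per-G means of a structural parameter with the forward design-equation
#' expectation overlaid.
#'
#' @param object An [ensemble_table][run_ensemble()].
#' @param parameter `"V"`, `"E"`, `"epsilon"` or `"chi"`.
#' @param eqset A [design_equations()] set for the overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_table <- function(object, parameter = c("V", "E",
                                                          "epsilon", "chi"),
                                    eqset = design_equations(), ...) {
  parameter <- match.arg(parameter)
  means <- dplyr::summarise(dplyr::group_by(as_tibble(object), .data$G),
                            value = mean(.data[[parameter]]),
                            .groups = "drop")
  L <- if ("L" %in% names(object)) object$L[1] else 100
  grid <- expected_metrics_from_g(seq(min(object$G), max(object$G),
                                      length.out = 200), L = L, eqset = eqset)
  ycol <- switch(parameter, V = "V_hat", E = "E_hat",
                 epsilon = "epsilon_hat", chi = "chi_hat")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$G, y = .data$value)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data[[ycol]]),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "generating points G", y = parameter,
                  title = sprintf("Per-G mean %s with design-equation expectation",
                                  parameter))
}

#' Plot a case-study report
#'
#' Distribution of the achieved structural parameter per generating-point
#' level, with the design target marked.
#'
#' @param object A [case_study()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.case_study <- function(object, ...) {
  par <- object$target$parameter
  df <- as_tibble(object$table)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$G),
                                   y = .data[[par]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = object$target$value, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "generating points G", y = par,
                  title = sprintf("Case study '%s': target %s = %g",
                                  object$kind, par, object$target$value))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
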