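## ggplot2 visualisations for the main result types.

#' Plot a scattering profile
#'
#' Log-intensity versus momentum transfer, with an uncertainty ribbon when
#' sigma values are informative.
#'
#' @param object A [scattering_profile()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.scattering_profile <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$I > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$I - .data$sigma, .Machine$double.xmin),
                                      ymax = .data$I + .data$sigma),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u.)",
                  title = "Scattering profile")
}

#' Plot a normalized Kratky curve
#'
#' Dimensionless Kratky transform with the compact-reference peak
#' (`x = sqrt(3)`, `y = 3/e`) marked for comparison; elongated particles
#' peak to the right of it.
#'
#' @param object A [normalized_kratky()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.kratky_curve <- function(object, ...) {
  pk <- kratky_peak(object)
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = sqrt(3), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = 3 / exp(1), linetype = "dotted") +
    ggplot2::annotate("point", x = pk[["x"]], y = pk[["y"]], shape = 1, size = 3) +
    ggplot2::labs(x = expression(q ~ R[g]), y = expression((q ~ R[g])^2 ~ I(q) / I(0)),
                  title = "Normalized Kratky plot")
}

#' Plot a bundle model as an axial profile
#'
#' Radial distance from the C3 axis against axial position, coloured by
#' segment and faceted by chain: a quick visual check that the flipping
#' helices extend (long state) or fold back (short state).
#'
#' @param model A [bundle_model()].
#' @return A ggplot object.
#' @export
plot_bundle <- function(model) {
  d <- dplyr::mutate(tibble::as_tibble(model),
                     radius = sqrt(.data$x^2 + .data$y^2))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$radius, y = .data$z,
                                  colour = .data$segment)) +
    ggplot2::geom_path(ggplot2::aes(group = .data$chain), alpha = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~chain) +
    ggplot2::labs(x = "distance from C3 axis (Å)", y = "z (Å)",
                  title = sprintf("Bundle model (%s state)", state_tag(model)))
}

#' Plot state-preference scores of all layer configurations
#'
#' @param scores Output of [score_all_configs()].
#' @return A ggplot object.
#' @export
plot_config_scores <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = stats::reorder(.data$code, .data$score),
                                       y = .data$score, fill = .data$preference)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "layer configuration (hinge-proximal first)",
                  y = "state-preference score (negative = short)",
                  title = "Interface-layer state preference")
}
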