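# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_raster geom_errorbar labs scale_fill_viridis_c coord_equal
#'   theme_minimal
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.free_energy_profile <- function(object, ...) {
  ggplot(object$table, aes(x = .data$mean_N, y = .data$F_kT)) +
    geom_line() + geom_point() +
    labs(x = expression(langle * tilde(N)[v] * rangle),
         y = "F (kT)",
         title = "Sparse-sampling free energy of dewetting") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pmf_profile <- function(object, ...) {
  p <- ggplot(object$table, aes(x = .data$z, y = .data$W))
  if (!all(is.na(object$table$err))) {
    p <- p + geom_ribbon(aes(ymin = .data$W - .data$err,
                             ymax = .data$W + .data$err), alpha = 0.25)
  }
  p + geom_line() +
    labs(x = "z (nm)", y = "W(z) (kcal/mol)",
         title = "Potential of mean force") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.density_map_2d <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, fill = .data$density)) +
    geom_raster() + coord_equal() +
    scale_fill_viridis_c(name = expression("molecules/nm"^3)) +
    labs(x = "x (nm)", y = "y (nm)", title = "Interfacial water density") +
    theme_minimal()
}

#' Plot the normalized water-number response
#'
#' @param response Output of [normalized_response()].
#' @return A ggplot.
#' @export
plot_response <- function(response) {
  ggplot(response, aes(x = .data$beta_phi, y = .data$response)) +
    geom_errorbar(aes(ymin = .data$response - .data$sem,
                      ymax = .data$response + .data$sem), width = 0) +
    geom_line() + geom_point() +
    labs(x = expression(beta * phi), y = expression(N / N[0]),
         title = "Water-number response to the linear bias") +
    theme_minimal()
}
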