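#' Plot a solved similarity profile
#'
#' Velocity `F'`, stream-function variable `F` and temperature `theta`
#' against the similarity coordinate eta.
#'
#' @param object an `hnf_profile`.
#' @param vars which variables to draw.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hnf_profile
#' @export
autoplot.hnf_profile <- function(object, vars = c("Fp", "F", "theta"), ...) {
  long <- tidyr::pivot_longer(object$profile,
                              cols = dplyr::all_of(vars),
                              names_to = "variable", values_to = "value")
  long$variable <- factor(long$variable, levels = vars,
                          labels = vars)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$eta, y = .data$value,
                                     colour = .data$variable)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = expression(eta), y = NULL, colour = NULL,
      title = sprintf("gamma = %g, Pr = %g, phi1 = %g, phi2 = %g (%s)",
                      object$params$gamma, object$params$pr,
                      object$params$phi1, object$params$phi2,
                      object$params$closure)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a wall-quantity sweep
#'
#' One line per swept quantity against the chosen parameter.
#'
#' @param sweep a tibble from [run_sweep()].
#' @param x name of the parameter column on the x axis.
#' @param y wall quantity column, `"nu_scaled"` or `"cf_scaled"`.
#' @return a ggplot object.
#' @export
plot_sweep <- function(sweep, x = "gamma", y = "nu_scaled") {
  stopifnot(x %in% names(sweep), y %in% names(sweep))
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = x, y = y) +
    ggplot2::theme_minimal()
}

#' Plot the stenosis shape
#'
#' @param eps severity in \[0, 1).
#' @param n sample points.
#' @return a ggplot object showing the dimensionless vessel wall.
#' @export
plot_stenosis <- function(eps = 0.5, n = 201) {
  tab <- geometry_table(eps, n)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$x_tilde, y = .data$f)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = -.data$f)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = expression(tilde(x)), y = expression(R / R[0])) +
    ggplot2::theme_minimal()
}
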