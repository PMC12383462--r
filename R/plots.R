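#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods for the main result types: voltage densities,
#' Fokker-Planck solutions, wavefunction Born densities, trajectory
#' ensembles, circuit outcome distributions, and the equivalence-experiment
#' overlay (empirical histogram against the \eqn{|\psi|^2} curve, plus the
#' Fokker-Planck reference when present).
#'
#' @param object A package result object.
#' @param n_show For ensembles, number of trajectories drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @name quantneuron-plots
NULL

#' @rdname quantneuron-plots
#' @export
autoplot.density_estimate <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$v, .data$density)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "steelblue",
                      alpha = 0.7) +
    ggplot2::labs(x = "membrane potential v", y = "density") +
    ggplot2::theme_minimal()
}

#' @rdname quantneuron-plots
#' @export
autoplot.fp_solution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$v, .data$rho)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "membrane potential v", y = expression(rho(v)),
                  subtitle = sprintf("t = %g", attr(object, "time"))) +
    ggplot2::theme_minimal()
}

#' @rdname quantneuron-plots
#' @export
autoplot.wavefunction <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$v, .data$rho)) +
    ggplot2::geom_line(colour = "darkorchid") +
    ggplot2::labs(x = "membrane potential v", y = expression("|" * psi * "|"^2),
                  subtitle = sprintf("t = %g, hbar = %.4g", object$time,
                                     as.numeric(object$hbar))) +
    ggplot2::theme_minimal()
}

#' @rdname quantneuron-plots
#' @export
autoplot.fhn_ensemble <- function(object, n_show = 50, ...) {
  df <- as_tibble(object)
  keep <- df$traj_id <= min(n_show, nrow(object$v))
  ggplot2::ggplot(df[keep, ],
                  ggplot2::aes(.data$t, .data$v, group = .data$traj_id)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::labs(x = "time", y = "membrane potential v") +
    ggplot2::theme_minimal()
}

#' @rdname quantneuron-plots
#' @export
autoplot.prob_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$state, .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("basis state (%s-endian)",
                              attr(object, "bit_order")),
                  y = "probability") +
    ggplot2::theme_minimal()
}

#' @rdname quantneuron-plots
#' @export
autoplot.equivalence_report <- function(object, ...) {
  dens <- object$densities
  mc <- dplyr::filter(dens, .data$source == "mc")
  curves <- dplyr::filter(dens, .data$source != "mc")
  ggplot2::ggplot() +
    ggplot2::geom_col(data = mc, ggplot2::aes(.data$v, .data$density),
                      width = diff(mc$v[1:2]), fill = "steelblue",
                      alpha = 0.5) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(.data$v, .data$density,
                                    colour = .data$source),
                       linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(psi2 = "firebrick", fp = "darkgreen"),
      labels = c(psi2 = expression("|" * psi * "|"^2), fp = "Fokker-Planck")) +
    ggplot2::labs(x = "membrane potential v", y = "density",
                  colour = NULL,
                  subtitle = sprintf("terminal densities, t = %g",
                                     object$config$fhn$t_final)) +
    ggplot2::theme_minimal()
}
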