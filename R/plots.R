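#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the probability mass function of the maximum clonal size
#'
#' Lollipop plot of \eqn{P(X^{max} = i_\varrho)} over the truncated
#' support. In establishment regimes the characteristic bimodal shape —
#' one mode at the initial size (early extinction), one far away
#' (establishment in the periphery) — is directly visible; `log_y` helps
#' when the modes differ by orders of magnitude.
#'
#' @param object An [xmax_distribution()].
#' @param log_y Log-scale the probability axis.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xmax_distribution <- function(object, log_y = FALSE, ...) {
  df <- object$pmf
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$pmf)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$size, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "maximum clonal size (cells)",
      y = "probability",
      title = sprintf("Maximum clonal size from %d cell%s (mass covered: %.3f)",
                      object$i0, if (object$i0 > 1) "s" else "",
                      object$covered_mass)
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a simulated clonotype trajectory
#'
#' Step plot of the clonal size over time for one Gillespie path.
#'
#' @param object A [simulate_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clone_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$size)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (mean T cell lifetimes)",
                  y = "clonal size (cells)")
}

#' Plot contraction-time means with standard-deviation ribbons
#'
#' Mean time to contract to the target size, plus/minus one standard
#' deviation, as a function of the start size.
#'
#' @param object A [contraction_moments()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contraction_moments <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "initial clonal size (cells)",
      y = sprintf("time to contract to %d (mean T cell lifetimes)",
                  object$i_rho)
    )
}
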