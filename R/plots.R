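#' Plot a mean-field phase diagram
#'
#' Raster of one computed quantity over the swept plane with the critical
#' line overlaid (dashed) and, in the `beta-dJ` plane, the
#' zero-temperature critical heterogeneity (dotted).
#'
#' @param object An [phase_diagram_sweep()] result.
#' @param quantity Column to display: `"m"`, `"q"`, `"s_cond"`, `"s_rev"`
#'   or `"sigma"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sk_phase_grid
#' @export
autoplot.sk_phase_grid <- function(object, quantity = "sigma", ...) {
  plane <- attr(object, "plane")
  crit <- attr(object, "critical")
  yvar <- if (plane == "beta-dJ") "dj" else "dh"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$beta, y = .data[[yvar]],
                                    fill = .data[[quantity]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = quantity) +
    ggplot2::labs(x = expression(beta),
                  y = if (yvar == "dj") expression(Delta * J)
                      else expression(Delta * H))
  if (nrow(crit) > 0) {
    p <- p + ggplot2::geom_line(
      data = crit[is.finite(crit$value), ],
      ggplot2::aes(x = .data$beta, y = .data$value),
      inherit.aes = FALSE, linetype = "dashed", colour = "white")
  }
  if (plane == "beta-dJ") {
    p <- p + ggplot2::geom_hline(yintercept = sqrt(2 / pi) * object$j0[1],
                                 linetype = "dotted", colour = "white")
  }
  p
}

#' Plot the transient asynchronous magnetization
#'
#' @param object An [integrate_async_dynamics()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sk_async_dynamics
#' @export
autoplot.sk_async_dynamics <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$time, y = .data$m)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$m, linetype = "dashed") +
    ggplot2::labs(x = "time (sweeps)", y = "m(t)")
}

#' Plot a finite-size convergence study
#'
#' Estimator values with 2-SE ribbons against the mean-field curve.
#'
#' @param object A [convergence_study()] tibble.
#' @param quantity `"m"`, `"q"` or `"sigma"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_convergence <- function(object, quantity = "m", ...) {
  est <- paste0(quantity, "_hat")
  se <- paste0(quantity, "_se")
  th <- paste0(quantity, "_theory")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_line(ggplot2::aes(y = .data[[th]]), colour = "black") +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data[[est]],
                   ymin = .data[[est]] - 2 * .data[[se]],
                   ymax = .data[[est]] + 2 * .data[[se]],
                   colour = factor(.data$n_spins)),
      size = 0.3) +
    ggplot2::labs(colour = "N", y = quantity, x = expression(beta))
}
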