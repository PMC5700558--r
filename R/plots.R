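#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' Time series of the three compartments on a free y scale, with pulse
#' instants marked.
#'
#' @param object A `tim_trajectory` from [simulate_pulsed()].
#' @param compartments Which compartments to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tim_trajectory <- function(object,
                                    compartments = c("x", "y", "z"),
                                    ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time", "x", "y", "z", "pulse")],
    cols = c("x", "y", "z"),
    names_to = "compartment", values_to = "volume"
  )
  df <- dplyr::filter(df, .data$compartment %in% compartments)
  labs <- c(
    x = "tumor (x)", y = "CD4+ T cells (y)", z = "cytokine (z)"
  )
  df$compartment <- factor(
    labs[df$compartment],
    levels = labs[compartments]
  )
  pulses <- unique(object$time[object$pulse])
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$volume)) +
    ggplot2::geom_vline(
      xintercept = pulses, linetype = "dotted", colour = "grey70"
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~compartment, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = expression(volume ~ (cm^3))) +
    ggplot2::theme_minimal()
}

#' Plot a one-parameter attractor sweep
#'
#' Tumor extrema over the attractor against the swept parameter, the
#' standard one-parameter bifurcation-diagram view: coincident min and
#' max indicate a fixed point, a band indicates an oscillation.
#'
#' @param object A `tim_sweep` from [sweep_parameter()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tim_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$value, group = .data$init_id)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$x_min, ymax = .data$x_max),
      fill = "grey80"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$x_rep, colour = .data$kind),
      size = 0.9
    ) +
    ggplot2::labs(
      x = attr(object, "sweep"), y = expression(tumor ~ volume ~ (cm^3)),
      colour = "attractor"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-parameter region map
#'
#' Classified grid points coloured by region signature (the set of
#' coexisting stroboscopic-map fixed points with stability), with the
#' unresolved boundary cells outlined.
#'
#' @param object A `tim_region_map` from [region_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tim_region_map <- function(object, ...) {
  pts <- object$points
  pts <- dplyr::left_join(pts, object$regions, by = "signature")
  pts$region <- factor(paste0("R", pts$region_id))
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$p1, .data$p2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$region), size = 1.2) +
    ggplot2::labs(x = object$axes[1], y = object$axes[2]) +
    ggplot2::theme_minimal()
  bc <- object$boundary_cells
  if (nrow(bc) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = bc,
      ggplot2::aes(
        xmin = .data$p1_lo, xmax = .data$p1_hi,
        ymin = .data$p2_lo, ymax = .data$p2_hi
      ),
      inherit.aes = FALSE, fill = NA, colour = "grey40",
      linewidth = 0.2
    )
  }
  p
}

#' Plot the analytic bifurcation surfaces
#'
#' Shows the Hopf surface b(m, beta) as filled contours over the
#' (m, beta) plane together with the (vertical) transcritical plane
#' beta = beta_c as a reference line.
#'
#' @param surfaces Output of [three_parameter_surfaces()].
#' @param params The [tim_params()] used to generate it (for beta_c).
#' @return A ggplot object.
#' @export
plot_surfaces <- function(surfaces, params) {
  hopf <- dplyr::filter(surfaces, .data$surface == "hopf")
  ggplot2::ggplot(hopf, ggplot2::aes(.data$m, .data$beta, z = .data$b)) +
    ggplot2::geom_contour_filled(bins = 10) +
    ggplot2::geom_hline(
      yintercept = beta_crit(params), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "m (cm^3)", y = "beta (day^-1)", fill = "Hopf b (cm^3)"
    ) +
    ggplot2::theme_minimal()
}
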