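#' @export
autoplot.pk_deltaz <- function(object, z_upper = NULL, z_lower = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_ps, .data$delta_z_A)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (ps)", y = expression(Delta * Z ~ "(Å)"),
                  title = "Permeation coordinate") +
    ggplot2::theme_minimal()
  if (!is.null(z_upper)) p <- p + ggplot2::geom_hline(yintercept = z_upper,
                                                      linetype = "dashed")
  if (!is.null(z_lower)) p <- p + ggplot2::geom_hline(yintercept = z_lower,
                                                      linetype = "dashed")
  p
}

#' @export
autoplot.pk_pore_profile <- function(object, ...) {
  bn <- bottlenecks(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$z_A, .data$radius_A)) +
    ggplot2::geom_line(color = "darkgreen") +
    ggplot2::labs(x = "channel z (Å)", y = "pore radius (Å)",
                  title = "Pore-radius profile") +
    ggplot2::theme_minimal()
  if (nrow(bn) > 0) {
    p <- p + ggplot2::geom_point(data = bn, color = "red", size = 2)
  }
  p
}

#' @export
autoplot.pk_contacts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ps, .data$count,
                                       color = factor(.data$target))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "hydrophobic lipid contacts",
                  color = "residue", title = "Lipid contact numbers") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pk_ion_disp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dz_A)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", color = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "mean_dz"),
                        color = "red", linetype = "dashed") +
    ggplot2::labs(x = expression(Delta * z ~ "(Å)"), y = "ions",
                  title = "Ion displacement along Z") +
    ggplot2::theme_minimal()
}
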