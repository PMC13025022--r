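#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a vibrational density of states
#'
#' @param object a `vdos_spectrum` tibble from [total_vdos()] or
#'   [mode_projected_vdos()]
#' @param xlim optional wavenumber range (cm^-1)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.vdos_spectrum <- function(object, xlim = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$freq, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(nu ~ (cm^-1)),
                  y = "VDoS (kJ/mol per cm⁻¹)")
  if (!is.null(xlim)) p <- p + ggplot2::coord_cartesian(xlim = xlim)
  p
}

#' Plot a free-energy surface
#'
#' 2D surfaces are drawn as filled free-energy maps (masked bins blank);
#' 1D surfaces as profiles with a ribbon for the replica standard error
#' when available.
#'
#' @param object a `free_energy_surface`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.free_energy_surface <- function(object, ...) {
  td <- tidy(object)
  if (length(object$vars) == 2L) {
    ggplot2::ggplot(td, ggplot2::aes(x = .data[[object$vars[1]]],
                                     y = .data[[object$vars[2]]],
                                     fill = .data$F)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white",
                                    name = "F (kJ/mol)") +
      ggplot2::labs(x = object$vars[1], y = object$vars[2])
  } else {
    p <- ggplot2::ggplot(td, ggplot2::aes(x = .data[[object$vars[1]]],
                                          y = .data$F))
    if (!all(is.na(td$sem)))
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$F - .data$sem,
                     ymax = .data$F + .data$sem), alpha = 0.3)
    p + ggplot2::geom_line() +
      ggplot2::labs(x = object$vars[1], y = "F (kJ/mol)")
  }
}

#' Heatmap of replica mode correlations
#'
#' One tile per mode pair and replica pair, the visual form in which mode
#' reproducibility across replicas is usually inspected.
#'
#' @param object a [replica_report()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.replica_report <- function(object, ...) {
  rows <- list()
  for (nm in names(object$mode_cor)) {
    M <- object$mode_cor[[nm]]
    df <- expand.grid(mode_a = rownames(M), mode_b = colnames(M))
    df$correlation <- as.numeric(M)
    df$pair <- nm
    rows[[nm]] <- df
  }
  td <- do.call(rbind, rows)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mode_b, y = .data$mode_a,
                                   fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~pair) +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "|corr|")
}

#' Minimum free-energy path profile plot
#'
#' @param path tibble from [min_free_energy_path()]
#' @return a ggplot with standard-deviation and SEM error bands
#' @export
plot_mfep <- function(path) {
  p <- ggplot2::ggplot(path, ggplot2::aes(x = .data$step, y = .data$F))
  if (!all(is.na(path$std)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$F - .data$std,
                   ymax = .data$F + .data$std), alpha = 0.2)
  if (!all(is.na(path$sem)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$F - .data$sem,
                   ymax = .data$F + .data$sem), alpha = 0.4)
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "path step", y = "F (kJ/mol)")
}
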