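#' Plot a slice of a solvation grid
#'
#' Heatmap of one grid field on the voxel layer nearest a given z.
#'
#' @param object A finalized `cav_gist`.
#' @param field Field to plot (default `"g"`).
#' @param z Slice position, Angstrom (default: grid mid-plane).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cav_gist <- function(object, field = "g", z = NULL, ...) {
  if (!field %in% gist_fields(object)) abort(paste0("unknown field '", field, "'"))
  spec <- object$spec
  z <- z %||% (spec$origin[3] + spec$shape[3] * spec$spacing / 2)
  iz <- min(max(floor((z - spec$origin[3]) / spec$spacing), 0), spec$shape[3] - 1)
  a <- object[[field]][, , iz + 1]
  df <- tidyr::expand_grid(ix = seq_len(spec$shape[1]) - 1,
                           iy = seq_len(spec$shape[2]) - 1)
  df <- dplyr::arrange(df, .data$iy, .data$ix)
  df$value <- as.vector(a)
  df$x <- spec$origin[1] + (df$ix + 0.5) * spec$spacing
  df$y <- spec$origin[2] + (df$iy + 0.5) * spec$spacing
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Å)", y = "y (Å)",
                  title = sprintf("%s at z = %.1f Å", field,
                                  spec$origin[3] + (iz + 0.5) * spec$spacing)) +
    ggplot2::theme_minimal()
}

#' Plot a rigid-vs-flexible comparison
#'
#' Bar chart of the rigid - flexible deltas, with block-SEM error bars when
#' available.
#'
#' @param object A `cav_comparison`.
#' @param quantities Quantities to show (default: energy and H-bond totals).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cav_comparison <- function(object,
                                    quantities = c("e_tot", "e_sw", "e_ww",
                                                   "hb_sw", "hb_ww"), ...) {
  df <- dplyr::filter(tidy(object), .data$quantity %in% quantities)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$quantity, .data$delta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "rigid - flexible",
                  title = "Rigid vs flexible subvolume deltas") +
    ggplot2::theme_minimal()
  if ("delta_sem" %in% names(df)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta - .data$delta_sem,
                   ymax = .data$delta + .data$delta_sem), width = 0.2)
  }
  p
}

#' Integrated quantities against subvolume distance
#'
#' Line plot of an integrated quantity over a range of subvolume distances,
#' optionally split by system.
#'
#' @param profile Tibble with columns `distance`, the quantity, and
#'   optionally `system`.
#' @param quantity Column to plot (default `"e_tot_per_water"`).
#' @return A ggplot object.
#' @export
plot_subvolume_profile <- function(profile, quantity = "e_tot_per_water") {
  aes <- if ("system" %in% names(profile)) {
    ggplot2::aes(.data$distance, .data[[quantity]], colour = .data$system)
  } else {
    ggplot2::aes(.data$distance, .data[[quantity]])
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "subvolume distance (Å)", y = quantity) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
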