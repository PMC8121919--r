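#' Plot the loadings of a fitted morphospace
#'
#' Correlation-circle style plot of descriptor loadings on two principal
#' components.
#'
#' @param object A `snow_morphospace`.
#' @param components Two components to display (default PC1/PC2).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snow_morphospace
#' @export
autoplot.snow_morphospace <- function(object, components = c("PC1", "PC2"),
                                      ...) {
  ld <- as_tibble(object$rotation) %>%
    mutate(variable = rownames(object$rotation))
  pct <- sprintf("%.0f%%", 100 * object$explained[
    match(components, colnames(object$rotation))])
  ggplot2::ggplot(ld, ggplot2::aes(
    x = .data[[components[1]]], y = .data[[components[2]]]
  )) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = 0, yend = 0),
      arrow = ggplot2::arrow(ends = "first",
                             length = ggplot2::unit(2, "mm")),
      colour = "grey40"
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$variable), size = 3) +
    ggplot2::labs(
      x = paste0(components[1], " (", pct[1], ")"),
      y = paste0(components[2], " (", pct[2], ")"),
      title = "Morphospace loadings"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter of morphospace coordinates coloured by morphotype
#'
#' @param scores Tibble with PC columns and (optionally) a `morphotype`
#'   column, e.g. from [assign_morphotypes()].
#' @param components Two components to display.
#' @return A ggplot object.
#' @export
plot_morphospace <- function(scores, components = c("PC1", "PC2")) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(
    x = .data[[components[1]]], y = .data[[components[2]]]
  ))
  if ("morphotype" %in% names(scores)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$morphotype),
                                 alpha = 0.5, size = 0.7)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.5, size = 0.7)
  }
  p + ggplot2::theme_minimal()
}

#' Depth-time section of morphotype concentrations
#'
#' Tile section (depth increasing downwards) of concentration over time,
#' one facet per morphotype — the standard way to display deepening
#' concentration peaks.
#'
#' @param profiles Long profile tibble from [bin_concentrations()] or
#'   [generate_field()].
#' @param trans Transformation for the fill scale (default `"sqrt"`).
#' @return A ggplot object.
#' @export
plot_profile_section <- function(profiles, trans = "sqrt") {
  ggplot2::ggplot(profiles, ggplot2::aes(
    x = .data$time, y = .data$depth_bin,
    fill = .data$concentration_per_L
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(trans = trans,
                                  name = expression(ind ~ L^-1)) +
    ggplot2::facet_wrap(~morphotype) +
    ggplot2::labs(x = "time (d)", y = "depth (m)") +
    ggplot2::theme_minimal()
}

#' Render a vignette as a ggplot raster
#'
#' @param vignette A [snow_vignette()].
#' @return A ggplot object.
#' @export
plot_vignette <- function(vignette) {
  px <- vignette$pixels
  df <- tidyr::crossing(row = seq_len(nrow(px)), col = seq_len(ncol(px)))
  df$grey <- as.vector(t(px))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$grey)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = vignette$object_id, x = NULL, y = NULL) +
    ggplot2::theme_void()
}
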