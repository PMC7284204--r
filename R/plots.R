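#' Plot a design raster
#'
#' @param design one-row `topo_library` tibble.
#' @param scale raster scale (px/um).
#' @return a ggplot object.
#' @export
plot_design <- function(design, scale = 10) {
  r <- render_design(design, scale)
  df <- tibble::tibble(x = as.vector(col(r)) / scale,
                       y = as.vector(row(r)) / scale,
                       pillar = as.vector(r) > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$pillar)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey95", "TRUE" = "grey20"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = design$design_id) +
    ggplot2::theme_minimal()
}

#' Plot a chip layout
#'
#' Duplicate pairs share a color; flat controls are highlighted.
#'
#' @param layout a `topo_layout`.
#' @return a ggplot object.
#' @export
plot_chip_layout <- function(layout) {
  df <- dplyr::mutate(tibble::as_tibble(layout),
                      fill = ifelse(.data$is_flat, NA_integer_,
                                    as.integer(factor(.data$design_id))))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$fill), color = NA) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$is_flat),
                        color = "red", size = 0.8) +
    ggplot2::scale_fill_viridis_c(guide = "none", na.value = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row",
                  subtitle = "flat controls in red; duplicate pairs share a color") +
    ggplot2::theme_minimal()
}

#' Autoplot a screen summary
#'
#' Ratio versus attachment, colored by phenotype class when present
#' (mirroring the standard phenotype-attachment scatter of high-content
#' topography screens).
#'
#' @param object a `topo_summary`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot topo_summary
#' @export
autoplot.topo_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$attach_mean, .data$ratio))
  p <- if ("phenotype_class" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$phenotype_class),
                            alpha = 0.6)
  } else {
    p + ggplot2::geom_point(alpha = 0.6)
  }
  p + ggplot2::geom_hline(yintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::labs(x = "mean attachment (flat-normalized)",
                  y = "M2/M1 ratio (flat-normalized)") +
    ggplot2::theme_minimal()
}

#' Autoplot a fitted topography model
#'
#' Horizontal bar chart of the top Shapley-ranked descriptors by mean
#' absolute attribution.
#'
#' @param object a `topo_model`.
#' @param top_n number of features shown (default 15).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot topo_model
#' @export
autoplot.topo_model <- function(object, top_n = 15, ...) {
  r <- head(tidy(object), top_n)
  r$feature <- factor(r$feature, levels = rev(r$feature))
  ggplot2::ggplot(r, ggplot2::aes(.data$mean_abs_shap, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |Shapley attribution|", y = NULL,
                  title = sprintf("%s on %s (R² test = %.2f)",
                                  object$family, object$target, object$r2_test)) +
    ggplot2::theme_minimal()
}

#' Plot inscribed spacing circles over a working raster
#'
#' @param circles a `topo_circles` from [max_inscribed_circles()].
#' @return a ggplot object.
#' @export
plot_inscribed_circles <- function(circles) {
  df <- tibble::as_tibble(circles)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, size = .data$diameter_px)) +
    ggplot2::geom_point(shape = 1, color = "steelblue") +
    ggplot2::scale_size_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (working px)", y = "row (working px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
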