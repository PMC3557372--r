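#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot occurrence records in climate space
#'
#' Scatter of record scores on two retained axes, colored by species —
#' the climate-space counterpart of a distribution map.
#'
#' @param scores A tibble with `axis*` columns and a `species` column
#'   (e.g. [project_scores()] output on harmonized records).
#' @param axes Length-2 integer choice of axes to plot.
#' @return A ggplot.
#' @export
plot_climate_scores <- function(scores, axes = c(1, 2)) {
  ax <- paste0("axis", axes)
  check_columns(scores, c(ax, "species"), "scores")
  ggplot2::ggplot(scores, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                       colour = .data$species)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = paste("Climate axis", axes[1]),
                  y = paste("Climate axis", axes[2]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_climate_space Scree-style plot of variance explained.
#' @param object,... Climate space and unused arguments (autoplot method).
#' @export
autoplot.climate_space <- function(object, ...) {
  ve <- variance_explained(object)
  ggplot2::ggplot(ve, ggplot2::aes(.data$axis, .data$prop_var)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Axis", y = "Proportion of variance") +
    ggplot2::theme_minimal()
}

#' @describeIn niche_density Tile map of the occupancy surface `z` on the
#'   first two axes (2-D grids).
#' @param object,... Density and unused arguments (autoplot method).
#' @export
autoplot.niche_density <- function(object, ...) {
  if (object$grid$d != 2) {
    rlang::abort("autoplot supports 2-D grids; tidy() the density instead")
  }
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$axis1, .data$axis2, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = object$species, x = "Climate axis 1",
                  y = "Climate axis 2", fill = "z") +
    ggplot2::theme_minimal()
}

#' @describeIn equivalency_test Histogram of the permutation null with the
#'   observed D marked.
#' @param object,... Test object and unused arguments (autoplot method).
#' @export
autoplot.equivalency_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$null_D)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$D, colour = "red") +
    ggplot2::labs(x = "Null Schoener's D", y = "Replicates",
                  subtitle = sprintf("observed D = %.3f, p = %.4f",
                                     object$D, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @describeIn kmeans_classify Tile map of the category labels.
#' @param object,... Classification and unused arguments (autoplot
#'   method).
#' @export
autoplot.habitat_classification <- function(object, ...) {
  d <- dim(object$labels)
  df <- tibble::tibble(
    lon = rep(object$origin[1] + (seq_len(d[2]) - 1) * object$cell_size,
              each = d[1]),
    lat = rep(object$origin[2] + (seq_len(d[1]) - 1) * object$cell_size,
              times = d[2]),
    category = factor(as.integer(object$labels))
  )
  ggplot2::ggplot(df[!is.na(df$category), ],
                  ggplot2::aes(.data$lon, .data$lat,
                               fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Category") +
    ggplot2::theme_minimal()
}

#' Map per-cell percentages of a species' records on the hex grid
#'
#' @param hex A tibble from [hex_percentages()] (optionally filtered to
#'   one or a few species).
#' @return A ggplot of cell centers sized/colored by percentage, faceted
#'   by species.
#' @export
plot_hex_percentages <- function(hex) {
  check_columns(hex, c("species", "center_lon", "center_lat", "pct"),
                "hex")
  ggplot2::ggplot(hex, ggplot2::aes(.data$center_lon, .data$center_lat,
                                    colour = .data$pct)) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::facet_wrap(~species) +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "% of records") +
    ggplot2::theme_minimal()
}

#' Tile plot of a pairwise Schoener's D table
#'
#' @param d_table A tibble from [overlap_matrix()].
#' @return A ggplot tile map of the upper triangle.
#' @export
plot_overlap_matrix <- function(d_table) {
  check_columns(d_table, c("species_1", "species_2", "D"), "d_table")
  ggplot2::ggplot(d_table, ggplot2::aes(.data$species_1, .data$species_2,
                                        fill = .data$D)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$D)),
                       size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "D") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
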