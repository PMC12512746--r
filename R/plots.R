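#' Plot a movement network over space
#'
#' Nodes at their station coordinates sized by degree; directed edges drawn
#' as segments with width scaled by betweenness (min-max within the
#' network). Requires the network's nodes to carry coordinates (built with
#' `stations =`).
#'
#' @param object A `movement_network`.
#' @param length_mode Betweenness length mode.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot movement_network
#' @export
autoplot.movement_network <- function(object, length_mode = "inverse_count", ...) {
  nodes <- object$nodes
  coord_cols <- if (all(c("x_m", "y_m") %in% names(nodes))) c("x_m", "y_m")
    else if (all(c("longitude", "latitude") %in% names(nodes))) c("longitude", "latitude")
    else abort("network nodes carry no coordinates; build with `stations = `")
  nodes$.x <- nodes[[coord_cols[1]]]; nodes$.y <- nodes[[coord_cols[2]]]
  deg <- degree_centrality(object)
  nodes <- left_join(nodes, deg, by = "station_id")
  eb <- edge_betweenness(object, length_mode)
  seg <- eb %>%
    left_join(select(nodes, "station_id", x0 = ".x", y0 = ".y"),
              by = c(from = "station_id")) %>%
    left_join(select(nodes, "station_id", x1 = ".x", y1 = ".y"),
              by = c(to = "station_id"))
  p <- ggplot2::ggplot()
  if (nrow(seg) > 0) {
    rng <- range(seg$betweenness)
    seg$b_scaled <- if (diff(rng) > 0) (seg$betweenness - rng[1]) / diff(rng) else 1
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linewidth = .data$b_scaled),
      colour = "steelblue4", alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))
    ) + ggplot2::scale_linewidth(range = c(0.2, 1.6), name = "betweenness\n(scaled)")
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$.x, .data$.y, size = .data$degree),
                        colour = "coral3") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = coord_cols[1], y = coord_cols[2],
                  title = sprintf("movement network (%s)",
                                  paste(unlist(object$stratum), collapse = "/"))) +
    ggplot2::theme_minimal()
}

#' Plot relative influence of the habitat model's predictors
#'
#' @param object A `habitat_gbm`.
#' @param ... Unused.
#' @return A ggplot bar chart of relative influence (%).
#' @method autoplot habitat_gbm
#' @export
autoplot.habitat_gbm <- function(object, ...) {
  imp <- object$importance
  ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$relative_influence,
    y = stats::reorder(.data$predictor, .data$relative_influence)
  )) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = "relative influence (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a habitat scene
#'
#' Raster of the habitat classes with receiver stations overlaid when
#' supplied.
#'
#' @param object A `habitat_scene`.
#' @param stations Optional station tibble with `x_m`, `y_m`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot habitat_scene
#' @export
autoplot.habitat_scene <- function(object, stations = NULL, ...) {
  cc <- cell_centres(object)
  df <- tidyr::expand_grid(y = cc$y, x = cc$x)
  df$class <- object$class_names[as.character(as.vector(t(object$class_grid)))]
  # expand_grid varies x fastest within y, matching row-major traversal
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c(
      open_water = "#20415f", forereef = "#3d7ea6", reef_crest = "#c9b178",
      passage = "#7fb4d6", sand = "#e8dcb8", coral = "#c96f4a")) +
    ggplot2::theme_minimal()
  if (!is.null(stations)) {
    p <- p + ggplot2::geom_point(data = stations,
                                 ggplot2::aes(.data$x_m, .data$y_m),
                                 inherit.aes = FALSE, shape = 21,
                                 fill = "white", size = 2)
  }
  p
}
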