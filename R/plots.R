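#' Plot a network projection colored by a per-segment variable
#'
#' Draws the maximum-extent 2D projection of the network (x-y by default)
#' with each segment as a line, line width scaled by diameter and color by
#' the chosen variable.
#'
#' @param net A [vascular_network()].
#' @param values Optional named/per-segment numeric vector or tibble
#'   (`id`, `value`) to color by; defaults to diameter.
#' @param label Legend title.
#' @param axes Which coordinate pair to project onto, e.g. `c("x", "y")`.
#' @return A ggplot object.
#' @export
plot_network <- function(net, values = NULL, label = "diameter (um)",
                         axes = c("x", "y")) {
  stopifnot(inherits(net, "vascular_network"))
  segs <- net$segments
  nodes <- net$nodes
  if (is.null(values)) {
    v <- segs$diameter
  } else if (is.data.frame(values)) {
    v <- values$value[match(segs$id, values$id)]
  } else {
    v <- rep_len(as.numeric(values), nrow(segs))
  }
  df <- tibble(
    x = nodes[[axes[1]]][match(segs$node_i, nodes$id)],
    y = nodes[[axes[2]]][match(segs$node_i, nodes$id)],
    xend = nodes[[axes[1]]][match(segs$node_j, nodes$id)],
    yend = nodes[[axes[2]]][match(segs$node_j, nodes$id)],
    value = v, diameter = segs$diameter
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   xend = .data$xend, yend = .data$yend,
                                   color = .data$value,
                                   linewidth = .data$diameter)) +
    ggplot2::geom_segment(lineend = "round") +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::scale_color_viridis_c(name = label) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste0(axes[1], " (um)"), y = paste0(axes[2], " (um)")) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_network Autoplot of a hemodynamic state (blood flow
#'   magnitude, log10 scale).
#' @param object A `hemodynamic_state`.
#' @param variable Segment column to display.
#' @param ... Unused.
#' @method autoplot hemodynamic_state
#' @export
autoplot.hemodynamic_state <- function(object, variable = "flow", ...) {
  v <- object$segments[[variable]]
  if (variable == "flow") {
    v <- log10(pmax(abs(v), 1e-12))
    lab <- "log10 |Q| (ul/s)"
  } else {
    lab <- variable
  }
  plot_network(object$network, tibble(id = object$segments$id, value = v),
               label = lab)
}

#' @describeIn plot_network Autoplot of an oxygen state (segment PO2).
#' @method autoplot oxygen_state
#' @export
autoplot.oxygen_state <- function(object, ...) {
  plot_network(object$network,
               tibble(id = object$segments$id, value = object$segments$po2),
               label = "PO2 (mmHg)")
}

#' Plot a voxel-grid slice
#'
#' Heatmap of one z-slice of a [voxel_grid()] (e.g. a distance or density
#' map).
#'
#' @param grid A [voxel_grid()].
#' @param slice z index (default: middle slice).
#' @param label Fill legend title.
#' @return A ggplot object.
#' @export
plot_map_slice <- function(grid, slice = NULL, label = "value") {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid)
  slice <- slice %||% ceiling(d[3] / 2)
  sp <- attr(grid, "spacing")
  or <- attr(grid, "origin")
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$x <- or[1] + (df$i - 1) * sp[1]
  df$y <- or[2] + (df$j - 1) * sp[2]
  df$value <- as.numeric(grid[cbind(df$i, df$j, slice)])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = label) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_map_slice Autoplot of morphometry maps: D_v slice.
#' @param object A `morphometry_maps` result.
#' @param which One of `"d_v"`, `"l_v"`, `"s_v"`.
#' @param ... Passed to [plot_map_slice()].
#' @method autoplot morphometry_maps
#' @export
autoplot.morphometry_maps <- function(object, which = "d_v", ...) {
  labs <- c(d_v = "D_v (um)", l_v = "L_v (mm/mm^3)", s_v = "S_v (mm^2/mm^3)")
  plot_map_slice(object[[which]], label = labs[[which]], ...)
}

#' Dendrogram of a network clustering
#'
#' @param object A [cluster_networks()] result.
#' @param ... Unused.
#' @return A ggplot object drawing the UPGMA dendrogram with merge heights
#'   on the x axis (leaves to the right), with the cophenetic coefficient
#'   in the caption.
#' @method autoplot network_clustering
#' @export
autoplot.network_clustering <- function(object, ...) {
  tree <- object$tree
  n <- length(tree$order)
  # leaf y positions by dendrogram order
  leaf_y <- setNames(seq_len(n), tree$order)
  pos <- matrix(NA_real_, nrow(tree$merge), 2)  # y, height of each cluster
  segments <- list()
  cluster_y <- function(k) {
    if (k < 0) c(leaf_y[[as.character(-k)]], 0) else pos[k, ]
  }
  for (m in seq_len(nrow(tree$merge))) {
    a <- cluster_y(tree$merge[m, 1])
    b <- cluster_y(tree$merge[m, 2])
    h <- tree$height[m]
    ym <- (a[1] + b[1]) / 2
    pos[m, ] <- c(ym, h)
    segments[[length(segments) + 1]] <- tibble(
      x = c(a[2], b[2], h), xend = c(h, h, h),
      y = c(a[1], b[1], a[1]), yend = c(a[1], b[1], b[1])
    )
  }
  seg_df <- bind_rows(segments)
  lab_df <- tibble(y = seq_len(n), name = tree$labels[tree$order])
  ggplot2::ggplot(seg_df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = lab_df,
                       ggplot2::aes(x = -0.02 * max(tree$height),
                                    y = .data$y, label = .data$name),
                       hjust = 1, size = 3) +
    ggplot2::scale_x_continuous(limits = c(-0.35 * max(tree$height), NA)) +
    ggplot2::labs(x = "UPGMA merge distance", y = NULL,
                  caption = sprintf("cophenetic correlation %.3f",
                                    object$cophenetic)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}
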