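#' Tidy a tripartite network
#'
#' @param x A `trip_network`.
#' @param ... Unused.
#' @return The edge table as a plain tibble.
#' @export
tidy.trip_network <- function(x, ...) {
  as_tibble(x$edges)
}

#' One-row summary of a tripartite network
#'
#' @param x A `trip_network`.
#' @param ... Unused.
#' @return A one-row tibble: kind, alpha, node/edge counts per block, and the
#'   number of IBS > HC edges.
#' @export
glance.trip_network <- function(x, ...) {
  tibble(kind = x$kind, alpha = x$alpha,
         n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_microbe = sum(x$nodes$block == "microbe"),
         n_brain = sum(x$nodes$block == "brain"),
         n_phenotype = sum(x$nodes$block == "phenotype"),
         n_ibs_gt_hc = sum(x$edges$direction > 0))
}

#' Plot a tripartite network
#'
#' Nodes are laid out with a (seeded, hence reproducible) force-directed
#' layout, shaped/coloured by block; difference-network edges are red when
#' the IBS correlation exceeds the HC one (`z_diff > 0`) and blue otherwise.
#'
#' @param object A `trip_network`.
#' @param seed Layout seed.
#' @param label Draw node labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trip_network <- function(object, seed = 1L, label = TRUE, ...) {
  nodes <- object$nodes
  edges <- object$edges
  if (!nrow(nodes)) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "empty network") +
             ggplot2::theme_void())
  }
  g <- trip_network_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  lay <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  nodes <- left_join(nodes, lay, by = "name")
  if (nrow(edges)) {
    edges <- edges |>
      left_join(rename(lay, xa = "x", ya = "y"), by = c(var_a = "name")) |>
      left_join(rename(lay, xb = "x", yb = "y"), by = c(var_b = "name")) |>
      mutate(side = ifelse(.data$z_diff > 0, "IBS > HC", "IBS < HC"))
  }
  p <- ggplot2::ggplot()
  if (nrow(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
                   colour = .data$side),
      linewidth = 0.6, alpha = 0.8) +
      ggplot2::scale_colour_manual(
        values = c("IBS > HC" = "#c0392b", "IBS < HC" = "#2e6da4"),
        name = NULL)
  }
  p <- p + ggplot2::geom_point(
    data = nodes,
    ggplot2::aes(x = .data$x, y = .data$y, shape = .data$block, fill = .data$block),
    size = 3, colour = "grey20") +
    ggplot2::scale_shape_manual(values = c(microbe = 21, brain = 22, phenotype = 24))
  if (label) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
      size = 2.6, vjust = -1.1)
  }
  p + ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s network (alpha = %g)", object$kind, object$alpha))
}

#' Volcano-style plot of an edge table
#'
#' Group-difference Z statistics against `-log10(p_diff)` for every computed
#' edge, coloured by direction, with the significance threshold drawn.
#'
#' @param object A `trip_edges` tibble from [correlate_all()].
#' @param alpha Threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trip_edges <- function(object, alpha = 0.05, ...) {
  d <- as_tibble(object) |>
    mutate(side = ifelse(.data$z_diff > 0, "IBS > HC", "IBS < HC"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_diff, y = -log10(.data$p_diff),
                                  colour = .data$side)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c("IBS > HC" = "#c0392b", "IBS < HC" = "#2e6da4"), name = NULL) +
    ggplot2::labs(x = "Fisher z difference (IBS - HC)",
                  y = expression(-log[10](p[diff]))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 ggplot
NULL
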