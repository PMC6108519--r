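# ggplot2 displays: network layout with signed edges, CV loss curve,
# community sizes. Layouts come from igraph (Fruchterman-Reingold) under a
# fixed seed so plots are reproducible.

#' Plot a partial-correlation network
#'
#' Solid edges are positive, dashed negative; width scales with `|pcor|`;
#' nodes outside any `>= 3`-node component are hollow.
#'
#' @param object A `pcor_network`.
#' @param seed Layout seed.
#' @param label_nodes Draw node labels?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcor_network <- function(object, seed = 1L, label_nodes = TRUE, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes %>%
    mutate(x = xy[, 1], y = xy[, 2])
  edges <- object$edges %>%
    mutate(x = nodes$x[match(.data$from, nodes$node)],
           y = nodes$y[match(.data$from, nodes$node)],
           xend = nodes$x[match(.data$to, nodes$node)],
           yend = nodes$y[match(.data$to, nodes$node)],
           sign = ifelse(.data$pcor >= 0, "positive", "negative"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$sign,
                   linewidth = abs(.data$pcor)),
      colour = "grey40") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$in_network),
      size = 3, colour = "steelblue4") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "in network") +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), guide = "none") +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dashed"), name = "sign") +
    ggplot2::theme_void()
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1, size = 2.7)
  }
  p
}

#' Plot the cross-validation loss path
#'
#' Held-out negative log-likelihood against `log(lambda)` with the
#' selected penalty marked.
#'
#' @param object A `cv_glasso`.
#' @param ... Unused.
#' @export
autoplot.cv_glasso <- function(object, ...) {
  ggplot2::ggplot(object$path,
                  ggplot2::aes(x = log(.data$lambda), y = .data$mean_loss)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = log(object$lambda_opt),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "log(lambda)", y = "held-out negative log-likelihood",
                  title = sprintf("%d-fold CV, lambda* = %.4f",
                                  object$k, object$lambda_opt)) +
    ggplot2::theme_minimal()
}

#' Plot community sizes and overlap
#'
#' Bar chart of nodes per community; overlapping nodes (centrality >= 2)
#' are annotated in the subtitle.
#'
#' @param object A `link_communities` result.
#' @param ... Unused.
#' @export
autoplot.link_communities <- function(object, ...) {
  cc <- community_centrality(object)
  central <- cc$node[cc$central]
  ggplot2::ggplot(object$communities,
                  ggplot2::aes(x = factor(.data$community),
                               y = .data$n_nodes)) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(
      x = "community", y = "nodes",
      title = sprintf("%d link communities (D = %.3f)",
                      nrow(object$communities), object$density),
      subtitle = if (length(central)) {
        paste("central:", paste(central, collapse = ", "))
      } else "no overlapping nodes") +
    ggplot2::theme_minimal()
}
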