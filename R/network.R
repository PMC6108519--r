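#' Partial-correlation network from a precision fit
#'
#' Converts the penalized precision matrix into a signed weighted graph:
#' `pcor_ij = -omega_ij / sqrt(omega_ii * omega_jj)`. An edge exists where
#' the precision entry is numerically nonzero (`|pcor| > zero_tol`, exact-
#' zero support of the lasso — no correlation threshold). Partial
#' correlations of magnitude `>= strong_cutoff` (0.30) are flagged strong.
#' Connected components are computed; components spanning at least
#' `min_network_size` (3) nodes are the reported "networks", smaller
#' leftovers (isolated nodes, dyads) are kept but not counted as networks.
#'
#' @param fit A [glasso_fit()] (or a precision matrix).
#' @param labels Node labels; defaults to the fit's.
#' @param zero_tol Support tolerance (default 1e-8).
#' @param strong_cutoff Strong-edge threshold on `|pcor|` (default 0.30,
#'   boundary inclusive).
#' @param min_network_size Minimum component size to count as a network.
#' @return Object of class `pcor_network`: list with tibbles `nodes`
#'   (`node`, `component`, `component_size`, `in_network`, `degree`) and
#'   `edges` (`from`, `to`, `pcor`, `strong`, `component`), the `pcor`
#'   matrix, `n_networks`, and the thresholds used.
#' @export
partial_correlations <- function(fit, labels = NULL, zero_tol = 1e-8,
                                 strong_cutoff = 0.30, min_network_size = 3L) {
  omega <- if (inherits(fit, "glasso_fit")) fit$omega else fit
  p <- ncol(omega)
  if (is.null(labels)) {
    labels <- colnames(omega) %||% sprintf("V%d", seq_len(p))
  }
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * outer(d, d)
  diag(pc) <- 1
  pc <- 0.5 * (pc + t(pc))
  dimnames(pc) <- list(labels, labels)

  idx <- which(upper.tri(pc) & abs(pc) > zero_tol, arr.ind = TRUE)
  edges <- tibble(
    from = labels[idx[, 1L]],
    to = labels[idx[, 2L]],
    pcor = pc[idx]
  ) %>%
    arrange(.data$from, .data$to) %>%
    mutate(strong = abs(.data$pcor) >= strong_cutoff)

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = labels))
  comp <- igraph::components(g)
  nodes <- tibble(
    node = labels,
    component = comp$membership[labels],
    component_size = comp$csize[comp$membership[labels]],
    degree = igraph::degree(g)[labels]
  ) %>%
    mutate(in_network = .data$component_size >= min_network_size)
  edges <- edges %>%
    mutate(component = nodes$component[match(.data$from, nodes$node)])

  structure(
    list(nodes = nodes, edges = edges, pcor = pc,
         n_networks = sum(tapply(nodes$component_size, nodes$component,
                                 unique) >= min_network_size),
         zero_tol = zero_tol, strong_cutoff = strong_cutoff,
         min_network_size = min_network_size),
    class = "pcor_network"
  )
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf(
    "<pcor_network> %d nodes, %d edges (%d strong), %d network(s) of >= %d nodes\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$strong), x$n_networks,
    x$min_network_size))
  invisible(x)
}

#' Edge keys of a network (pair + sign)
#'
#' Normalized (lexicographic pair order) signed edge identities used by
#' the comparison module. By default only edges inside components of at
#' least `min_network_size` nodes count — the same rule under which the
#' reported networks are defined.
#'
#' @param net A `pcor_network`.
#' @param networks_only Restrict to components counted as networks?
#' @return Tibble `from`, `to`, `sign` (+1/-1), `pcor`.
#' @export
network_edge_keys <- function(net, networks_only = TRUE) {
  stopifnot(inherits(net, "pcor_network"))
  e <- net$edges
  if (networks_only) {
    sizes <- net$nodes$component_size[match(e$from, net$nodes$node)]
    e <- e[sizes >= net$min_network_size, , drop = FALSE]
  }
  a <- pmin(e$from, e$to)
  b <- pmax(e$from, e$to)
  ord <- order(a, b)
  tibble::new_tibble(list(from = a[ord], to = b[ord],
                          sign = as.integer(sign(e$pcor[ord])),
                          pcor = e$pcor[ord]), nrow = length(ord))
}

#' Convert a network to an igraph object
#'
#' Edge attributes `pcor` and `strong`; node attributes `component` and
#' `in_network` (plus `community_count` if `communities` is supplied).
#'
#' @param net A `pcor_network`.
#' @param communities Optional [link_communities()] result for node
#'   annotation.
#' @return An igraph graph.
#' @export
as_igraph <- function(net, communities = NULL) {
  stopifnot(inherits(net, "pcor_network"))
  v <- as.data.frame(net$nodes[, c("node", "component", "in_network")])
  names(v)[1] <- "name"
  if (!is.null(communities)) {
    cc <- community_centrality(communities)
    v$community_count <- cc$n_communities[match(v$name, cc$node)]
  }
  igraph::graph_from_data_frame(
    as.data.frame(net$edges[, c("from", "to", "pcor", "strong")]),
    directed = FALSE, vertices = v)
}
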