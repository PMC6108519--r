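# Overlapping community detection on edges: Jaccard similarity of the
# inclusive neighborhoods of the non-shared endpoints, single-linkage
# agglomeration, dendrogram cut at maximum partition density. Nodes
# inherit (possibly multiple) memberships from the edge clusters they
# touch; clusters spanning fewer than 3 nodes are not communities, so a
# connected dyad can legitimately end up unassigned.

# normalized edge table (from < to, character) from various inputs
edge_table <- function(x) {
  e <- if (inherits(x, "pcor_network")) x$edges[, c("from", "to")]
  else if (inherits(x, "link_dendrogram")) x$edges
  else as_tibble(x)[, c("from", "to")]
  e <- e %>%
    mutate(from = as.character(.data$from), to = as.character(.data$to)) %>%
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) %>%
    select(from = "a", to = "b") %>%
    arrange(.data$from, .data$to)
  if (any(e$from == e$to)) abort("Self-loops are not allowed.")
  if (anyDuplicated(e)) abort("Duplicate edges are not allowed.")
  e
}

inclusive_neighborhoods <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  nb <- setNames(lapply(nodes, function(v) v), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, unique)
}

#' Similarity between two edges
#'
#' Edges sharing a node `k`, say `(i, k)` and `(j, k)`, are compared by the
#' Jaccard index of the inclusive neighborhoods `n+(i)` and `n+(j)` of
#' their non-shared endpoints, where `n+(v) = {v} union neighbors(v)`.
#' Edges sharing no node have similarity 0.
#'
#' @param x A `pcor_network` or a data frame of edges (`from`, `to`).
#' @param e1,e2 Length-2 vectors naming the endpoints of each edge.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tri <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"))
#' edge_similarity(tri, c("a", "b"), c("a", "c"))
#' @export
edge_similarity <- function(x, e1, e2) {
  edges <- edge_table(x)
  nb <- inclusive_neighborhoods(edges)
  e1 <- as.character(e1); e2 <- as.character(e2)
  if (setequal(e1, e2)) abort("`e1` and `e2` must be distinct edges.")
  shared <- intersect(e1, e2)
  if (length(shared) == 0L) return(0)
  i <- setdiff(e1, shared); j <- setdiff(e2, shared)
  if (length(i) == 0L || length(j) == 0L) {
    # edges share both endpoints only if duplicated, already rejected
    return(1)
  }
  length(intersect(nb[[i]], nb[[j]])) / length(union(nb[[i]], nb[[j]]))
}

# M x M similarity matrix over the (sorted) edge list
edge_similarity_matrix <- function(edges) {
  nb <- inclusive_neighborhoods(edges)
  M <- nrow(edges)
  S <- matrix(0, M, M)
  # group edge indices by node
  by_node <- split(rep(seq_len(M), 2L), c(edges$from, edges$to))
  for (v in names(by_node)) {
    ids <- by_node[[v]]
    if (length(ids) < 2L) next
    ends <- ifelse(edges$from[ids] == v, edges$to[ids], edges$from[ids])
    for (ii in seq_along(ids)) {
      for (jj in seq_len(ii - 1L)) {
        a <- ends[ii]; b <- ends[jj]
        s <- if (a == b) 1 else {
          length(intersect(nb[[a]], nb[[b]])) / length(union(nb[[a]], nb[[b]]))
        }
        e1 <- ids[ii]; e2 <- ids[jj]
        S[e1, e2] <- max(S[e1, e2], s)
        S[e2, e1] <- S[e1, e2]
      }
    }
  }
  diag(S) <- 1
  S
}

#' Single-linkage dendrogram over the edge set
#'
#' Agglomerates edges by descending pairwise similarity (distance
#' `1 - similarity`) with single linkage; ties are resolved by the
#' lexicographic edge order, but every cut of a single-linkage tree equals
#' the connected components of the similarity graph thresholded at the cut
#' level, so partitions are tie-robust.
#'
#' @param x A `pcor_network` or edge data frame.
#' @return Object of class `link_dendrogram`: `edges`, `similarity`
#'   matrix, `hclust` (NULL when only one edge), `M`.
#' @export
link_dendrogram <- function(x) {
  edges <- edge_table(x)
  M <- nrow(edges)
  if (M < 1L) abort("Need at least one edge.")
  S <- edge_similarity_matrix(edges)
  hc <- if (M >= 2L) hclust(as.dist(1 - S), method = "single")
  structure(list(edges = edges, similarity = S, hclust = hc, M = M),
            class = "link_dendrogram")
}

#' Partition density of an edge clustering
#'
#' `D = (2/M) * sum_c m_c (m_c - n_c + 1) / ((n_c - 2)(n_c - 1))` over
#' clusters with `m_c` edges spanning `n_c` nodes; a cluster that is a
#' single edge (`n_c = 2`) contributes 0 by convention, and any tree
#' (`m_c = n_c - 1`) contributes 0 through the numerator.
#'
#' @param membership Integer cluster id per edge.
#' @param edges Edge data frame aligned with `membership`.
#' @return Partition density (scalar).
#' @export
partition_density <- function(membership, edges) {
  edges <- as_tibble(edges)
  M <- nrow(edges)
  stopifnot(length(membership) == M, M >= 1L)
  dc <- vapply(split(seq_len(M), membership), function(ids) {
    m_c <- length(ids)
    n_c <- length(unique(c(edges$from[ids], edges$to[ids])))
    if (n_c <= 2L) return(0)
    m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1))
  }, numeric(1))
  (2 / M) * sum(dc)
}

#' Cut the edge dendrogram at maximum partition density
#'
#' Evaluates the partition density at every merge level of the
#' single-linkage edge dendrogram (plus the all-singletons baseline) and
#' returns the partition at the maximizing level; exact ties break toward
#' the higher-similarity (finer) cut. Clusters spanning at least
#' `min_nodes` nodes are reported as communities — overlapping (a node can
#' sit in several) and possibly nested. Nodes touched by no community are
#' unassigned even if they carry edges.
#'
#' @param x A `pcor_network`, edge data frame, or `link_dendrogram`.
#' @param min_nodes Minimum spanned nodes for a cluster to be a community.
#' @return Object of class `link_communities`: `communities` tibble
#'   (`community`, `n_nodes`, `n_edges`, `density_contribution`, plus
#'   list-columns `nodes`, `edges`), `edge_membership` tibble, `density`,
#'   `cut_similarity`, `unassigned` nodes, `M`, `nodes` (all labels).
#' @export
link_communities <- function(x, min_nodes = 3L) {
  dend <- if (inherits(x, "link_dendrogram")) x else link_dendrogram(x)
  edges <- dend$edges
  M <- dend$M
  all_nodes <- sort(unique(c(edges$from, edges$to)))

  if (M == 1L) {
    membership <- 1L
    best_d <- 0
    cut_sim <- 1
  } else {
    heights <- sort(unique(dend$hclust$height))
    # candidate partitions: singletons, then each merge level (fine -> coarse)
    best_membership <- seq_len(M)
    best_d <- partition_density(best_membership, edges)
    cut_sim <- 1
    for (h in heights) {
      mem <- cutree(dend$hclust, h = h)
      d <- partition_density(mem, edges)
      if (d > best_d + 1e-12) {
        best_d <- d
        best_membership <- mem
        cut_sim <- 1 - h
      }
    }
    membership <- best_membership
  }

  clusters <- split(seq_len(M), membership)
  keep <- vapply(clusters, function(ids) {
    length(unique(c(edges$from[ids], edges$to[ids]))) >= min_nodes
  }, logical(1))
  comm_ids <- which(keep)

  communities <- purrr::map_dfr(seq_along(comm_ids), function(k) {
    ids <- clusters[[comm_ids[k]]]
    nodes <- sort(unique(c(edges$from[ids], edges$to[ids])))
    m_c <- length(ids); n_c <- length(nodes)
    tibble(community = k, n_nodes = n_c, n_edges = m_c,
           density_contribution =
             if (n_c <= 2L) 0 else m_c * (m_c - n_c + 1) / ((n_c - 2) * (n_c - 1)),
           nodes = list(nodes), edges = list(edges[ids, ]))
  })
  if (nrow(communities) == 0L) {
    communities <- tibble(community = integer(), n_nodes = integer(),
                          n_edges = integer(), density_contribution = numeric(),
                          nodes = list(), edges = list())
  }

  community_of_cluster <- rep(NA_integer_, length(clusters))
  community_of_cluster[comm_ids] <- seq_along(comm_ids)
  edge_membership <- edges %>%
    mutate(cluster = as.integer(factor(membership,
                                       levels = names(clusters))),
           community = community_of_cluster[.data$cluster])

  assigned <- sort(unique(unlist(communities$nodes)))
  structure(
    list(communities = communities, edge_membership = edge_membership,
         density = best_d, cut_similarity = cut_sim,
         unassigned = setdiff(all_nodes, assigned),
         nodes = all_nodes, M = M, min_nodes = min_nodes),
    class = "link_communities"
  )
}

#' @export
print.link_communities <- function(x, ...) {
  cat(sprintf(
    "<link_communities> %d communities from %d edges (D = %.3f); %d unassigned node(s)\n",
    nrow(x$communities), x$M, x$density, length(x$unassigned)))
  invisible(x)
}

#' Community-count centrality
#'
#' A node's centrality is the number of communities it belongs to; nodes
#' in two or more (`central`) sit at the seams of the network. Ranking is
#' descending by count with alphabetical tie order, so it is stable under
#' relabeling.
#'
#' @param partition A [link_communities()] result.
#' @return Tibble `node`, `n_communities`, `rank`, `central`, sorted by
#'   rank.
#' @export
community_centrality <- function(partition) {
  stopifnot(inherits(partition, "link_communities"))
  counts <- table(factor(unlist(partition$communities$nodes),
                         levels = partition$nodes))
  tibble(node = partition$nodes,
         n_communities = as.integer(counts[partition$nodes])) %>%
    arrange(dplyr::desc(.data$n_communities), .data$node) %>%
    mutate(rank = dplyr::row_number(),
           central = .data$n_communities >= 2L)
}

#' Brute-force community detection (testing oracle)
#'
#' Exhaustively maximizes the partition density, either over every
#' single-linkage cut level recomputed independently as connected
#' components of the thresholded edge-similarity graph (`mode =
#' "levels"`), or — for at most 6 edges — over all set partitions of the
#' edge set into connected clusters (`mode = "partitions"`). Intended as
#' an independent check of [link_communities()] on small graphs.
#'
#' @param x A `pcor_network` or edge data frame with at most 10 edges.
#' @param mode Search space (see above).
#' @param min_nodes Community filter, as in [link_communities()].
#' @return A list with `density`, `membership`, and `communities` (list of
#'   sorted node vectors of clusters spanning `>= min_nodes` nodes).
#' @export
brute_force_communities <- function(x, mode = c("levels", "partitions"),
                                    min_nodes = 3L) {
  mode <- match.arg(mode)
  edges <- edge_table(x)
  M <- nrow(edges)
  if (M > 10L) abort("Brute force supports at most 10 edges.")
  S <- edge_similarity_matrix(edges)

  score <- function(mem) partition_density(mem, edges)

  if (mode == "levels") {
    sims <- sort(unique(S[upper.tri(S)]), decreasing = TRUE)
    best_mem <- seq_len(M); best_d <- score(best_mem)
    for (s in sims) {
      adj <- S >= s
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               diag = FALSE)
      mem <- igraph::components(g)$membership
      d <- score(mem)
      if (d > best_d + 1e-12) { best_d <- d; best_mem <- mem }
    }
  } else {
    if (M > 6L) abort("`mode = \"partitions\"` supports at most 6 edges.")
    parts <- set_partitions(M)
    # a block must form a connected edge set
    connected_block <- function(ids) {
      if (length(ids) == 1L) return(TRUE)
      sub <- igraph::graph_from_data_frame(edges[ids, ], directed = FALSE)
      igraph::is_connected(sub)
    }
    best_mem <- seq_len(M); best_d <- score(best_mem)
    for (mem in parts) {
      ok <- all(vapply(split(seq_len(M), mem), connected_block, logical(1)))
      if (ok) {
        d <- score(mem)
        if (d > best_d + 1e-12) { best_d <- d; best_mem <- mem }
      }
    }
  }

  comms <- lapply(split(seq_len(M), best_mem), function(ids) {
    sort(unique(c(edges$from[ids], edges$to[ids])))
  })
  comms <- unname(comms[vapply(comms, length, integer(1)) >= min_nodes])
  list(density = best_d, membership = unname(best_mem), communities = comms)
}

# all set partitions of 1..n as membership vectors (restricted growth)
set_partitions <- function(n) {
  out <- list()
  rec <- function(mem, k) {
    i <- length(mem) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- mem; return(invisible()) }
    for (b in seq_len(k + 1L)) rec(c(mem, b), max(k, b))
  }
  rec(integer(), 0L)
  out
}
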