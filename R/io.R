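# Serialization of pipeline artifacts: TSV edge lists and tables, GraphML
# via igraph, JSON for CV diagnostics / communities / comparison reports.
# All writers are deterministic so runs at equal seeds are byte-identical.

#' Write / read an analysis table as TSV
#'
#' Group-name header preceded by the row-metadata columns
#' (`participant_id`, `recall_index` or `n_recalls`).
#'
#' @param table A `meal_table` or `habitual_table`.
#' @param path Output TSV path.
#' @export
write_intake_table <- function(table, path) {
  df <- as_tibble(table)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_intake_table
#' @param meal Meal label for a meal table; `NULL` restores a habitual
#'   table.
#' @export
read_intake_table <- function(path, meal = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- intersect(c("participant_id", "recall_index", "n_recalls"),
                         names(df))
  groups <- setdiff(names(df), meta_cols)
  cls <- if (is.null(meal)) "habitual_table" else "meal_table"
  structure(df, meal = meal, food_groups = groups,
            class = c(cls, class(df)))
}

#' Write a network as a TSV edge list
#'
#' Columns `source, target, pcor, strong`; deterministic lexicographic
#' order.
#'
#' @param net A `pcor_network`.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges %>%
    select(source = "from", target = "to", "pcor", "strong") %>%
    arrange(.data$source, .data$target)
  readr::write_tsv(e, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param nodes Optional full node-label vector (restores isolated nodes).
#' @return `read_edge_list()` returns a `pcor_network` rebuilt from the
#'   file (precision-specific fields absent).
#' @export
read_edge_list <- function(path, nodes = NULL) {
  e <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- nodes %||% sort(unique(c(e$source, e$target)))
  p <- length(labels)
  pc <- diag(1, p); dimnames(pc) <- list(labels, labels)
  if (nrow(e)) {
    pc[cbind(match(e$source, labels), match(e$target, labels))] <- e$pcor
    pc[cbind(match(e$target, labels), match(e$source, labels))] <- e$pcor
  }
  # rebuild via a pseudo-precision with matching support and pcor values
  omega <- diag(1, p) - (pc - diag(1, p))
  dimnames(omega) <- list(labels, labels)
  partial_correlations(omega, labels = labels)
}

#' Export a network (and optional communities) as GraphML
#'
#' @param net A `pcor_network`.
#' @param path Output path.
#' @param communities Optional [link_communities()] for node annotation.
#' @export
write_network_graphml <- function(net, path, communities = NULL) {
  g <- as_igraph(net, communities)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write communities as JSON
#'
#' One object per community (`id`, `nodes`, `edges`, `density_contribution`)
#' plus the partition density, cut level and unassigned nodes.
#'
#' @param communities A [link_communities()] result.
#' @param path Output path.
#' @export
write_communities_json <- function(communities, path) {
  comm <- purrr::pmap(communities$communities, function(community, n_nodes,
                                                        n_edges,
                                                        density_contribution,
                                                        nodes, edges) {
    list(id = community, nodes = nodes,
         edges = paste(edges$from, edges$to, sep = "--"),
         n_nodes = n_nodes, n_edges = n_edges,
         density_contribution = density_contribution)
  })
  jsonlite::write_json(
    list(partition_density = communities$density,
         cut_similarity = communities$cut_similarity,
         n_communities = nrow(communities$communities),
         communities = comm,
         unassigned = communities$unassigned),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write community-count centrality as TSV
#'
#' Columns `node, n_communities, rank`.
#'
#' @param centrality A [community_centrality()] tibble.
#' @param path Output path.
#' @export
write_centrality_tsv <- function(centrality, path) {
  readr::write_tsv(centrality[, c("node", "n_communities", "rank")], path)
  invisible(path)
}

#' Write CV diagnostics as JSON
#'
#' Grid, mean held-out losses, selected penalty and fold seed.
#'
#' @param cv A `cv_glasso` object.
#' @param path Output path.
#' @export
write_cv_json <- function(cv, path) {
  jsonlite::write_json(
    list(lambda = cv$path$lambda, mean_loss = cv$path$mean_loss,
         lambda_opt = cv$lambda_opt, k = cv$k, seed = cv$seed,
         method = cv$method),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write an overlap report as JSON and TSV
#'
#' `<stem>.json` holds the full report; `<stem>_overlap.tsv` and
#' `<stem>_discordant.tsv` the human-readable tables.
#'
#' @param report An [overlap_report()].
#' @param stem Path stem (no extension).
#' @export
write_overlap_report <- function(report, stem) {
  jsonlite::write_json(
    list(sign_specific = report$sign_specific,
         overlap = report$overlap,
         habitual_unique = report$habitual_unique,
         discordant = report$discordant,
         strength = report$strength),
    paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE, digits = NA,
    dataframe = "rows")
  readr::write_tsv(report$overlap, paste0(stem, "_overlap.tsv"))
  d <- report$discordant
  if (is.null(d) || nrow(d) == 0L) {
    d <- tibble(meal = character(), from = character(), to = character(),
                pcor_net = numeric(), pcor_reference = numeric())
  }
  readr::write_tsv(d, paste0(stem, "_discordant.tsv"))
  invisible(stem)
}
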