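# broom-style tidiers: tidy() rows are the natural unit of each object
# (edges, communities, grid points), glance() is a one-row summary.

#' @rdname tidy_mealnets
#' @export
tidy.pcor_network <- function(x, ...) {
  x$edges
}

#' @rdname tidy_mealnets
#' @export
glance.pcor_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_strong = sum(x$edges$strong), n_networks = x$n_networks,
         n_isolated = sum(x$nodes$degree == 0),
         mean_abs_pcor = if (nrow(x$edges)) mean(abs(x$edges$pcor)) else NA_real_,
         max_abs_pcor = if (nrow(x$edges)) max(abs(x$edges$pcor)) else NA_real_)
}

#' Tidiers for mealnets result objects
#'
#' [generics::tidy()] returns one row per edge (`pcor_network`), per
#' community (`link_communities`), per penalty-grid point (`cv_glasso`) or
#' per meal (`overlap_report`); [generics::glance()] returns a one-row
#' summary.
#'
#' @param x A fitted mealnets object.
#' @param ... Unused.
#' @name tidy_mealnets
#' @export
tidy.link_communities <- function(x, ...) {
  x$communities %>%
    mutate(nodes = purrr::map_chr(.data$nodes, paste, collapse = ", ")) %>%
    select("community", "n_nodes", "n_edges", "density_contribution", "nodes")
}

#' @rdname tidy_mealnets
#' @export
glance.link_communities <- function(x, ...) {
  tibble(n_communities = nrow(x$communities),
         partition_density = x$density,
         cut_similarity = x$cut_similarity,
         n_edges = x$M,
         n_unassigned = length(x$unassigned))
}

#' @rdname tidy_mealnets
#' @export
tidy.cv_glasso <- function(x, ...) {
  x$path
}

#' @rdname tidy_mealnets
#' @export
glance.cv_glasso <- function(x, ...) {
  tibble(lambda_opt = x$lambda_opt, k = x$k, seed = x$seed,
         method = x$method,
         min_mean_loss = min(x$path$mean_loss))
}

#' @rdname tidy_mealnets
#' @export
tidy.glasso_fit <- function(x, ...) {
  partial_correlations(x)$edges
}

#' @rdname tidy_mealnets
#' @export
glance.glasso_fit <- function(x, ...) {
  p <- ncol(x$omega)
  tibble(lambda = x$lambda, objective = x$objective,
         kkt_residual = x$kkt_residual, iterations = x$iterations,
         n_edges = sum(x$omega[upper.tri(x$omega)] != 0), p = p)
}

#' @rdname tidy_mealnets
#' @export
tidy.overlap_report <- function(x, ...) {
  x$overlap
}

#' @rdname tidy_mealnets
#' @export
glance.overlap_report <- function(x, ...) {
  tibble(mean_overlap_pct = mean(x$overlap$percentage, na.rm = TRUE),
         habitual_unique_pct = x$habitual_unique$percentage,
         n_discordant = if (is.null(x$discordant)) 0L else nrow(x$discordant),
         sign_specific = x$sign_specific)
}

#' @rdname tidy_mealnets
#' @export
tidy.dietary_network_fit <- function(x, ...) {
  tidy(x$network)
}

#' @rdname tidy_mealnets
#' @export
glance.dietary_network_fit <- function(x, ...) {
  dplyr::bind_cols(tibble(label = x$label, lambda_opt = x$cv$lambda_opt),
                   glance(x$network))
}
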