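# Meal-vs-habitual comparison: edges are matched as unordered node pairs
# with (by default) the sign of the partial correlation — "direction-
# specific" matching. Only edges inside components of >= 3 nodes (the
# reported networks) are compared; where a meal yields several such
# components they are pooled.

#' Direction-specific edge overlap between two networks
#'
#' What fraction of one network's edges (same unordered pair and, with
#' `sign_specific = TRUE`, same sign) also appear in a reference network —
#' used to measure how far each meal network is reflected in the habitual
#' network. All components of at least 3 nodes contribute edges.
#'
#' @param net A `pcor_network` (e.g. a meal network).
#' @param reference A `pcor_network` (e.g. the habitual network).
#' @param sign_specific Match sign as well as pair? (default TRUE)
#' @return Tibble `n_edges`, `n_matched`, `percentage` (one decimal;
#'   `NA` with `status = "empty"` when `net` has no network edges).
#' @examples
#' # three meal edges, one of which matches the habitual pair AND sign
#' @export
edge_overlap <- function(net, reference, sign_specific = TRUE) {
  a <- network_edge_keys(net)
  b <- network_edge_keys(reference)
  if (nrow(a) == 0L) {
    return(tibble(n_edges = 0L, n_matched = 0L, percentage = NA_real_,
                  status = "empty"))
  }
  matched <- edge_key_match(a, b, sign_specific)
  tibble(n_edges = nrow(a), n_matched = sum(matched),
         percentage = round(100 * sum(matched) / nrow(a), 1),
         status = "ok")
}

edge_key_match <- function(a, b, sign_specific = TRUE) {
  key <- function(e) {
    if (sign_specific) paste(e$from, e$to, e$sign) else paste(e$from, e$to)
  }
  key(a) %in% key(b)
}

#' Habitual-only relations
#'
#' Percentage of habitual network edges (pair-and-sign by default) absent
#' from the union of all meal networks' edges.
#'
#' @param habitual A `pcor_network`.
#' @param meal_nets List of meal `pcor_network`s.
#' @inheritParams edge_overlap
#' @return Tibble `n_edges`, `n_unique`, `percentage` (`NA` + `"empty"`
#'   status for an empty habitual network).
#' @export
habitual_unique <- function(habitual, meal_nets, sign_specific = TRUE) {
  h <- network_edge_keys(habitual)
  if (nrow(h) == 0L) {
    return(tibble(n_edges = 0L, n_unique = 0L, percentage = NA_real_,
                  status = "empty"))
  }
  pooled <- dplyr::bind_rows(lapply(meal_nets, network_edge_keys))
  matched <- edge_key_match(h, pooled, sign_specific)
  tibble(n_edges = nrow(h), n_unique = sum(!matched),
         percentage = round(100 * sum(!matched) / nrow(h), 1),
         status = "ok")
}

#' Sign-discordant pairs between two networks
#'
#' Node pairs carrying an edge in both networks but with opposite partial-
#' correlation signs (e.g. a pairing positive at a meal yet negative
#' habitually). Deterministic lexicographic order.
#'
#' @param net,reference `pcor_network`s.
#' @return Tibble `from`, `to`, `pcor_net`, `pcor_reference`.
#' @export
sign_discordance <- function(net, reference) {
  a <- network_edge_keys(net)
  b <- network_edge_keys(reference)
  dplyr::inner_join(a, b, by = c("from", "to"),
                    suffix = c("_net", "_reference")) %>%
    filter(.data$sign_net != .data$sign_reference) %>%
    select("from", "to", pcor_net = "pcor_net",
           pcor_reference = "pcor_reference") %>%
    arrange(.data$from, .data$to)
}

#' Edge-strength summary across networks
#'
#' Mean and maximum `|pcor|` over each network's edges — the quantity
#' behind the attenuation phenomenon (meal-level partial correlations are
#' stronger than habitual ones, since habitual averaging mixes occasions
#' and days).
#'
#' @param networks Named list of `pcor_network`s.
#' @return Tibble `network`, `n_edges`, `mean_abs_pcor`, `max_abs_pcor`
#'   (`NA`s and `status = "empty"` for edgeless networks).
#' @export
strength_comparison <- function(networks) {
  purrr::imap_dfr(networks, function(net, nm) {
    e <- network_edge_keys(net)
    if (nrow(e) == 0L) {
      tibble(network = nm, n_edges = 0L, mean_abs_pcor = NA_real_,
             max_abs_pcor = NA_real_, status = "empty")
    } else {
      tibble(network = nm, n_edges = nrow(e),
             mean_abs_pcor = mean(abs(e$pcor)),
             max_abs_pcor = max(abs(e$pcor)), status = "ok")
    }
  })
}

#' Full meal-vs-habitual overlap report
#'
#' Bundles [edge_overlap()] per meal, [habitual_unique()],
#' [sign_discordance()] per meal and [strength_comparison()] into one
#' object.
#'
#' @param meal_nets Named list of meal `pcor_network`s.
#' @param habitual The habitual `pcor_network`.
#' @inheritParams edge_overlap
#' @return Object of class `overlap_report` with elements `overlap`
#'   (tibble, one row per meal), `habitual_unique`, `discordant` (tibble
#'   with `meal` column), `strength`, `sign_specific`.
#' @export
overlap_report <- function(meal_nets, habitual, sign_specific = TRUE) {
  stopifnot(is.list(meal_nets), !is.null(names(meal_nets)))
  overlap <- purrr::imap_dfr(meal_nets, function(net, nm) {
    dplyr::bind_cols(tibble(meal = nm),
                     edge_overlap(net, habitual, sign_specific))
  })
  discordant <- purrr::imap_dfr(meal_nets, function(net, nm) {
    d <- sign_discordance(net, habitual)
    if (nrow(d)) dplyr::bind_cols(tibble(meal = nm), d) else NULL
  })
  structure(
    list(overlap = overlap,
         habitual_unique = habitual_unique(habitual, meal_nets, sign_specific),
         discordant = discordant,
         strength = strength_comparison(c(meal_nets,
                                          list(habitual = habitual))),
         sign_specific = sign_specific),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  for (i in seq_len(nrow(x$overlap))) {
    r <- x$overlap[i, ]
    cat(sprintf("  %-16s %s\n", r$meal,
                if (r$status == "empty") "empty network"
                else sprintf("%d/%d edges in habitual (%.1f%%)",
                             r$n_matched, r$n_edges, r$percentage)))
  }
  hu <- x$habitual_unique
  cat(sprintf("  habitual-only    %s\n",
              if (hu$status == "empty") "empty network"
              else sprintf("%d/%d edges (%.1f%%)", hu$n_unique, hu$n_edges,
                           hu$percentage)))
  invisible(x)
}
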