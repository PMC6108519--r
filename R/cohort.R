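#' Default eating occasions and food groups
#'
#' The recall protocol records intake in 11 eating occasions over the day,
#' four of which (breakfast, lunch, afternoon snack, dinner) are the main
#' meals analysed as separate networks. Intake is aggregated into 39 food
#' groups spanning staples, vegetables, fruits, dairy, meats, fats, sweets
#' and beverages.
#'
#' @return Character vectors of occasion labels (11) / group names (39).
#' @export
default_occasions <- function() {
  c("before breakfast", "breakfast", "morning snack", "lunch",
    "early afternoon", "afternoon snack", "before dinner", "dinner",
    "after dinner", "evening snack", "night")
}

#' @rdname default_occasions
#' @export
main_meals <- function() {
  c("breakfast", "lunch", "afternoon snack", "dinner")
}

#' @rdname default_occasions
#' @export
default_food_groups <- function() {
  meal_intake_moments()$food_group
}

#' Reference meal-level intake moments
#'
#' Per-food-group means and standard deviations of gram intake at the four
#' main meals in a German adult cohort assessed with repeated 24-hour
#' recalls; shipped as a plain-text table and used as calibration targets
#' for the synthetic-cohort margins.
#'
#' @return A tibble with `food_group` and `<meal>_mean` / `<meal>_sd`
#'   columns for breakfast, lunch, afternoon snack and dinner.
#' @export
meal_intake_moments <- function() {
  path <- system.file("extdata", "meal_intake_moments.csv",
                      package = "mealnets", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Specify a simulated recall cohort
#'
#' Bundles everything the generator needs: cohort size, the distribution of
#' recall days per participant, the 11 eating-occasion labels with the four
#' main meals, one latent dependence graph per meal, and the strength of the
#' within-person (day-to-day) latent correlation.
#'
#' @param n_participants Number of participants.
#' @param recalls_per_participant Probabilities over 1, 2 and 3 recall days
#'   (length-3 nonnegative vector summing to 1).
#' @param food_groups Character vector of food-group names.
#' @param occasions The 11 occasion labels; must contain `meals`.
#' @param meals The four main-meal labels.
#' @param meal_graphs Named list (one per meal) of [graph_spec()] objects
#'   with `n_nodes == length(food_groups)`.
#' @param participant_effect_sd Nonnegative scalar `s`; the latent meal
#'   vector is shared across a participant's days with correlation
#'   `rho = s^2 / (1 + s^2)`.
#' @param seed Integer seed used by [generate_recalls()] by default.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        recalls_per_participant = c(0, 0, 1),
                        food_groups = default_food_groups(),
                        occasions = default_occasions(),
                        meals = main_meals(),
                        meal_graphs,
                        participant_effect_sd = 1,
                        seed = 1L) {
  if (length(occasions) != 11L) {
    abort("`occasions` must contain exactly 11 labels.")
  }
  if (!all(meals %in% occasions)) {
    abort("Every main meal must be one of the 11 occasion labels.")
  }
  if (length(recalls_per_participant) != 3L ||
      any(recalls_per_participant < 0) ||
      abs(sum(recalls_per_participant) - 1) > 1e-8) {
    abort("`recalls_per_participant` must be probabilities over {1, 2, 3}.")
  }
  if (!is.list(meal_graphs) || !setequal(names(meal_graphs), meals)) {
    abort("`meal_graphs` must be a named list with one graph_spec per meal.")
  }
  for (m in meals) {
    g <- meal_graphs[[m]]
    if (!inherits(g, "graph_spec") || g$n_nodes != length(food_groups)) {
      abort(sprintf(
        "`meal_graphs[[\"%s\"]]` must be a graph_spec on %d nodes.",
        m, length(food_groups)))
    }
  }
  if (participant_effect_sd < 0) {
    abort("`participant_effect_sd` must be nonnegative.")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         recalls_per_participant = recalls_per_participant,
         food_groups = as.character(food_groups),
         occasions = as.character(occasions),
         meals = as.character(meals),
         meal_graphs = meal_graphs,
         participant_effect_sd = participant_effect_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Ready-made synthetic cohort emulating the reference study
#'
#' Returns a full simulation configuration: 814 participants with 3 recall
#' days each, 39 food groups, 11 eating occasions, one sparse latent graph
#' per main meal, and per-meal margins calibrated to the shipped
#' intake-moment table via [margins_from_moments()]. Meal graphs genuinely
#' differ by meal: each unordered pair of meals shares `n_shared_edges`
#' edges (with the same sign in both), and each meal additionally carries
#' `n_private_edges` of its own — no relation is common to all four meals,
#' mirroring how observed meal networks overlap only partially. Edge
#' partial correlations target `target_pcor` in magnitude with ~20%
#' negative signs.
#'
#' @param n_participants Cohort size (scale down for quick runs).
#' @param participant_effect_sd Within-person latent correlation control.
#' @param target_pcor True |partial correlation| on latent graph edges.
#' @param n_shared_edges Edges shared by each of the six meal pairs.
#' @param n_private_edges Additional meal-specific edges per meal.
#' @param seed Seed for graph construction and, by default, generation.
#' @return A list with elements `cohort` (a [cohort_spec()]) and `margins`
#'   (named list of per-meal [margin_spec()]s).
#' @export
cohort_preset <- function(n_participants = 814L, participant_effect_sd = 1,
                          target_pcor = 0.35, n_shared_edges = 4L,
                          n_private_edges = 12L, seed = 1L) {
  moments <- meal_intake_moments()
  groups <- moments$food_group
  p <- length(groups)
  meals <- main_meals()

  all_pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  all_pairs <- tibble(from = all_pairs[, 1L], to = all_pairs[, 2L])
  graphs <- withr::with_seed(seed + 1000L, {
    meal_pairs <- utils::combn(meals, 2L, simplify = FALSE)
    n_draw <- length(meal_pairs) * n_shared_edges +
      length(meals) * n_private_edges
    idx <- sample.int(nrow(all_pairs), n_draw)  # distinct pairs throughout
    signs <- ifelse(runif(n_draw) < 0.2, -1L, 1L)
    take <- function(k) {
      sel <- idx[seq_len(k)]; sg <- signs[seq_len(k)]
      idx <<- idx[-seq_len(k)]; signs <<- signs[-seq_len(k)]
      dplyr::bind_cols(all_pairs[sel, ], tibble(sign = sg))
    }
    shared <- lapply(meal_pairs, function(mp) take(n_shared_edges))
    private <- lapply(setNames(meals, meals),
                      function(m) take(n_private_edges))
    lapply(setNames(seq_along(meals), meals), function(k) {
      m <- meals[k]
      in_pair <- vapply(meal_pairs, function(mp) m %in% mp, logical(1))
      edges <- dplyr::bind_rows(c(shared[in_pair], private[m]))
      graph_spec(p, "custom", edges = edges, target_pcor = target_pcor,
                 seed = seed + k)
    })
  })

  meal_cols <- c(breakfast = "breakfast", lunch = "lunch",
                 `afternoon snack` = "afternoon_snack", dinner = "dinner")
  margins <- lapply(setNames(names(meal_cols), names(meal_cols)), function(m) {
    margins_from_moments(groups,
                         mean = moments[[paste0(meal_cols[[m]], "_mean")]],
                         sd = moments[[paste0(meal_cols[[m]], "_sd")]])
  })

  cohort <- cohort_spec(
    n_participants = n_participants,
    recalls_per_participant = c(0, 0, 1),
    food_groups = groups,
    meal_graphs = graphs,
    participant_effect_sd = participant_effect_sd,
    seed = seed
  )
  list(cohort = cohort, margins = margins)
}
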