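#' Build the meal-occurrence analysis table for one main meal
#'
#' A meal observation is a recall day on which anything at all was consumed
#' at that occasion (positive total grams, beverages included); skipped
#' meals contribute no row. Rows are recall days — deliberately not
#' aggregated per participant, so the table reflects foods eaten together
#' at actual meal occurrences. Columns are the full declared food-group
#' list in canonical order; groups not consumed at that meal stay as zero
#' columns so node sets match across meals.
#'
#' @param data A `recall_data` tibble (see [generate_recalls()],
#'   [read_recalls()]).
#' @param meal One of the main-meal occasion labels.
#' @return A tibble of class `meal_table`: `participant_id`, `recall_index`
#'   then one numeric column per food group; attribute `meal`.
#' @export
build_meal_table <- function(data, meal) {
  stopifnot(inherits(data, "recall_data"))
  groups <- attr(data, "food_groups")
  if (!meal %in% attr(data, "occasions")) {
    abort(sprintf("Unknown occasion \"%s\". Valid: %s.", meal,
                  toString(attr(data, "occasions"))))
  }
  rows <- as_tibble(data) %>%
    filter(.data$occasion == meal, .data$grams > 0) %>%
    group_by(.data$participant_id, .data$recall_index, .data$food_group) %>%
    summarise(grams = sum(.data$grams), .groups = "drop")
  wide <- pivot_groups(rows, groups)
  if (nrow(wide) < 2L) {
    abort(sprintf(
      "Fewer than 2 %s occurrences with positive intake: no correlation estimable.",
      meal))
  }
  structure(wide, meal = meal, food_groups = groups,
            class = c("meal_table", class(wide)))
}

#' Build the habitual (per-participant average daily) intake table
#'
#' For each participant and food group, grams are summed over all 11
#' eating occasions within each recall day, then averaged without weights
#' across the participant's available recall days. One row per participant.
#'
#' @param data A `recall_data` tibble.
#' @return A tibble of class `habitual_table`: `participant_id`,
#'   `n_recalls`, then one column of grams/day per food group.
#' @export
build_habitual_table <- function(data) {
  stopifnot(inherits(data, "recall_data"))
  groups <- attr(data, "food_groups")
  df <- as_tibble(data)
  n_recalls <- df %>%
    dplyr::distinct(.data$participant_id, .data$recall_index) %>%
    dplyr::count(.data$participant_id, name = "n_recalls")
  daily <- df %>%
    group_by(.data$participant_id, .data$food_group) %>%
    summarise(total = sum(.data$grams), .groups = "drop") %>%
    dplyr::left_join(n_recalls, by = "participant_id") %>%
    mutate(grams = .data$total / .data$n_recalls) %>%
    select("participant_id", "food_group", "grams")
  wide <- daily %>%
    mutate(recall_index = NA_integer_) %>%
    pivot_groups(groups) %>%
    select(-"recall_index") %>%
    dplyr::left_join(n_recalls, by = "participant_id") %>%
    dplyr::relocate("n_recalls", .after = "participant_id")
  structure(wide, food_groups = groups,
            class = c("habitual_table", class(wide)))
}

pivot_groups <- function(rows, groups) {
  wide <- rows %>%
    mutate(food_group = factor(.data$food_group, levels = groups)) %>%
    tidyr::pivot_wider(names_from = "food_group", values_from = "grams",
                       values_fill = 0, names_expand = TRUE)
  dplyr::arrange(wide, .data$participant_id, .data$recall_index)
}

#' Extract the numeric observation matrix from an analysis table
#'
#' @param table A `meal_table` or `habitual_table`.
#' @return Numeric matrix, observations x food groups.
#' @export
intake_matrix <- function(table) {
  groups <- attr(table, "food_groups")
  m <- as.matrix(as_tibble(table)[, groups])
  rownames(m) <- NULL
  m
}

#' Summarise intake by food group (mean and SD)
#'
#' Per-group mean and sample standard deviation (n - 1 denominator), the
#' standard descriptive reporting for intake tables.
#'
#' @param table A `meal_table` or `habitual_table`.
#' @return A tibble `food_group`, `mean`, `sd`, `n`.
#' @export
summarize_intake <- function(table) {
  m <- intake_matrix(table)
  if (nrow(m) == 0L) abort("Empty intake table.")
  tibble(
    food_group = colnames(m),
    mean = unname(colMeans(m)),
    sd = unname(apply(m, 2L, sd)),
    n = nrow(m)
  )
}
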