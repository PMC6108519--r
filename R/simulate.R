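#' Generate synthetic 24-hour recall records
#'
#' Simulates long-format recall data with a known dependence structure. For
#' each participant, recall day and main meal, a latent vector is drawn from
#' `N(0, Sigma_meal)` where `Sigma_meal` is the correlation matrix implied
#' by the meal's [make_precision()] graph. Day-to-day within-person
#' correlation enters as a shared latent fraction,
#' `z = sqrt(rho) u_participant + sqrt(1 - rho) v_day` with
#' `rho = s^2 / (1 + s^2)` from `participant_effect_sd = s`, so each meal's
#' marginal copula is exactly the specified one. Each latent coordinate is
#' mapped to grams by thresholding at the group's zero probability and
#' evaluating the positive-part quantile function above it; non-meal
#' occasions receive independent low-level noise draws. Only positive
#' amounts are recorded (absent rows mean zero intake), matching how recall
#' interviews store data.
#'
#' @param cohort A [cohort_spec()].
#' @param margins A [margin_spec()] used for every meal, or a named list
#'   with one margin_spec per meal label.
#' @param noise_margin Margins for the seven non-meal occasions; default is
#'   95% zeros with a small lognormal positive part (median ~10 g).
#' @param seed Integer seed; the dataset is byte-identical for equal seeds.
#' @return A tibble of class `recall_data` with columns `participant_id`,
#'   `recall_index`, `occasion`, `food_group`, `grams` and attributes
#'   `food_groups`, `occasions`, `meals`, `provenance`, `seed`.
#' @examples
#' preset <- cohort_preset(n_participants = 20)
#' rec <- generate_recalls(preset$cohort, preset$margins, seed = 1)
#' dplyr::count(rec, occasion)
#' @export
generate_recalls <- function(cohort, margins, noise_margin = NULL,
                             seed = cohort$seed) {
  stopifnot(inherits(cohort, "cohort_spec"))
  groups <- cohort$food_groups
  p <- length(groups)
  meals <- cohort$meals

  if (inherits(margins, "margin_spec")) {
    margins <- lapply(setNames(meals, meals), function(m) margins)
  }
  if (!setequal(names(margins), meals)) {
    abort("`margins` must be one margin_spec or a named list per meal.")
  }
  for (m in meals) {
    if (!identical(margins[[m]]$food_group, groups)) {
      abort(sprintf("Margins for \"%s\" must cover the cohort food groups in order.", m))
    }
  }
  if (is.null(noise_margin)) {
    noise_margin <- margin_spec(groups, zero_probability = 0.95,
                                par1 = log(10), par2 = 1)
  }

  rho <- cohort$participant_effect_sd^2 / (1 + cohort$participant_effect_sd^2)
  sigma_chol <- lapply(cohort$meal_graphs, function(g) {
    sigma <- stats::cov2cor(solve(make_precision(g)))
    chol(sigma)
  })

  withr::with_seed(seed, {
    n <- cohort$n_participants
    n_recalls <- sample(1:3, n, replace = TRUE,
                        prob = cohort$recalls_per_participant)
    days <- tibble(
      participant_id = rep(sprintf("P%04d", seq_len(n)), n_recalls),
      participant_index = rep(seq_len(n), n_recalls)
    ) %>%
      group_by(.data$participant_id) %>%
      mutate(recall_index = dplyr::row_number()) %>%
      ungroup()
    R <- nrow(days)

    pieces <- vector("list", length(meals) + 1L)
    for (mi in seq_along(meals)) {
      m <- meals[mi]
      U <- matrix(rnorm(n * p), n, p) %*% sigma_chol[[m]]
      V <- matrix(rnorm(R * p), R, p) %*% sigma_chol[[m]]
      Z <- sqrt(rho) * U[days$participant_index, , drop = FALSE] +
        sqrt(1 - rho) * V
      A <- amount_matrix(Z, margins[[m]])
      pieces[[mi]] <- melt_amounts(A, days, m, groups)
    }

    # unstructured small intakes at the seven non-meal occasions
    other <- setdiff(cohort$occasions, meals)
    noise_rows <- vector("list", length(other))
    for (oi in seq_along(other)) {
      Zo <- matrix(rnorm(R * p), R, p)
      Ao <- amount_matrix(Zo, noise_margin)
      noise_rows[[oi]] <- melt_amounts(Ao, days, other[oi], groups)
    }
    pieces[[length(meals) + 1L]] <- dplyr::bind_rows(noise_rows)

    out <- dplyr::bind_rows(pieces) %>%
      mutate(occasion = factor(.data$occasion, levels = cohort$occasions)) %>%
      arrange(.data$participant_id, .data$recall_index, .data$occasion,
              .data$food_group) %>%
      mutate(occasion = as.character(.data$occasion))
    new_recall_data(out, food_groups = groups, occasions = cohort$occasions,
                    meals = meals, provenance = "simulated", seed = seed)
  })
}

new_recall_data <- function(df, food_groups, occasions, meals,
                            provenance, seed = NULL) {
  structure(
    as_tibble(df),
    food_groups = food_groups, occasions = occasions, meals = meals,
    provenance = provenance, seed = seed,
    class = c("recall_data", class(as_tibble(df)))
  )
}

# map a latent-Gaussian matrix (rows = draws, cols = groups) to amounts
amount_matrix <- function(Z, margins) {
  U <- pnorm(Z)
  A <- matrix(0, nrow(Z), ncol(Z))
  for (j in seq_len(ncol(Z))) {
    pi0 <- margins$zero_probability[j]
    pos <- U[, j] >= pi0
    if (any(pos)) {
      v <- pmin((U[pos, j] - pi0) / (1 - pi0), 1 - 1e-12)
      A[pos, j] <- if (margins$family[j] == "lognormal") {
        qlnorm(v, margins$par1[j], margins$par2[j])
      } else {
        qgamma(v, shape = margins$par1[j], rate = margins$par2[j])
      }
    }
  }
  A
}

melt_amounts <- function(A, days, occasion, groups) {
  idx <- which(A > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  tibble(
    participant_id = days$participant_id[idx[, 1L]],
    recall_index = days$recall_index[idx[, 1L]],
    occasion = occasion,
    food_group = groups[idx[, 2L]],
    grams = A[idx]
  )
}

#' Simulate a single meal-occurrence matrix
#'
#' Draws `n` independent meal occurrences directly from a latent graph and
#' margins, bypassing the cohort machinery: useful for studying estimator
#' behaviour (e.g. structure recovery) at a chosen sample size.
#'
#' @param graph A [graph_spec()] (or a precision matrix).
#' @param margins A [margin_spec()] over the same number of nodes.
#' @param n Number of rows (meal occurrences).
#' @param seed Integer seed.
#' @return A numeric matrix `n x p` with the margin food groups as columns.
#' @export
simulate_meal_matrix <- function(graph, margins, n, seed = 1L) {
  omega <- if (inherits(graph, "graph_spec")) make_precision(graph) else graph
  sigma <- stats::cov2cor(solve(omega))
  p <- ncol(sigma)
  stopifnot(nrow(margins) == p)
  withr::with_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p) %*% chol(sigma)
    A <- amount_matrix(Z, margins)
    colnames(A) <- margins$food_group
    A
  })
}

#' Write / read recall datasets as tidy CSV
#'
#' `write_recalls()` writes the long records with header
#' `participant_id,recall_index,occasion,food_group,grams` plus a JSON
#' sidecar (`<path>.meta.json`) carrying the food-group list, occasion
#' list, provenance and seed. `read_recalls()` validates and restores a
#' `recall_data` object; duplicate keys are summed with a warning, negative
#' grams and unknown occasions are errors.
#'
#' @param data A `recall_data` tibble.
#' @param path CSV file path.
#' @export
write_recalls <- function(data, path) {
  stopifnot(inherits(data, "recall_data"))
  readr::write_csv(as_tibble(data)[, c("participant_id", "recall_index",
                                       "occasion", "food_group", "grams")],
                   path)
  meta <- list(food_groups = attr(data, "food_groups"),
               occasions = attr(data, "occasions"),
               meals = attr(data, "meals"),
               provenance = attr(data, "provenance"),
               seed = attr(data, "seed"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_recalls
#' @param path CSV file path written by `write_recalls()` or hand-made with
#'   the same header.
#' @param group_map Optional named character vector mapping raw food item
#'   labels to group names (a food-group map); unmapped items are an error.
#'   Default: identity on the declared food groups.
#' @param food_groups,occasions,meals Declared universes when no metadata
#'   sidecar is present.
#' @export
read_recalls <- function(path, group_map = NULL, food_groups = NULL,
                         occasions = NULL, meals = main_meals()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    recall_index = readr::col_integer(),
    occasion = readr::col_character(),
    food_group = readr::col_character(),
    grams = readr::col_double()
  ))
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
  if (is.null(food_groups)) {
    food_groups <- if (!is.null(meta)) meta$food_groups else default_food_groups()
  }
  if (is.null(occasions)) {
    occasions <- if (!is.null(meta)) meta$occasions else default_occasions()
  }

  bad <- which(is.na(df$grams) | df$grams < 0)
  if (length(bad)) {
    abort(sprintf("Negative or unparseable grams at data row %d.", bad[1L]))
  }
  if (!is.null(group_map)) {
    unmapped <- setdiff(unique(df$food_group), names(group_map))
    if (length(unmapped)) {
      abort(paste0("Unmapped food items: ", toString(head(unmapped, 5))))
    }
    df$food_group <- unname(group_map[df$food_group])
  }
  unknown_grp <- setdiff(unique(df$food_group), food_groups)
  if (length(unknown_grp)) {
    abort(paste0("Unknown food groups: ", toString(head(unknown_grp, 5))))
  }
  unknown_occ <- setdiff(unique(df$occasion), occasions)
  if (length(unknown_occ)) {
    abort(paste0("Unknown occasion label(s): ", toString(unknown_occ),
                 ". Valid labels: ", toString(occasions)))
  }

  dup <- duplicated(df[c("participant_id", "recall_index", "occasion",
                         "food_group")])
  if (any(dup)) {
    warn(sprintf("%d duplicate (participant, recall, occasion, group) rows summed.",
                 sum(dup)))
    df <- df %>%
      group_by(.data$participant_id, .data$recall_index, .data$occasion,
               .data$food_group) %>%
      summarise(grams = sum(.data$grams), .groups = "drop")
  }
  df <- df %>%
    mutate(occasion = factor(.data$occasion, levels = occasions)) %>%
    arrange(.data$participant_id, .data$recall_index, .data$occasion,
            .data$food_group) %>%
    mutate(occasion = as.character(.data$occasion))
  new_recall_data(df, food_groups = food_groups, occasions = occasions,
                  meals = meals,
                  provenance = if (!is.null(meta)) meta$provenance else "loaded",
                  seed = if (!is.null(meta)) meta$seed else NULL)
}
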