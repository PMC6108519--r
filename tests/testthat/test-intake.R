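groups4 <- c("Bread", "Butter & animal fat", "Coffee", "Tea")

long_row <- function(id, day, occ, grp, g) {
  tibble::tibble(participant_id = id, recall_index = day, occasion = occ,
                 food_group = grp, grams = g)
}

test_that("read_recalls validates, maps and de-duplicates", {
  df <- dplyr::bind_rows(
    long_row("P1", 1L, "breakfast", "Bread", 30),
    long_row("P1", 1L, "dinner", "Bread", 40),
    long_row("P2", 1L, "breakfast", "Coffee", 200)
  )
  rec <- recalls_from_df(df, groups4)
  expect_s3_class(rec, "recall_data")
  expect_equal(nrow(rec), 3L)

  # negative grams: error naming the data row
  bad <- df
  bad$grams[2] <- -1
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path)
  expect_error(read_recalls(path, food_groups = groups4), "row 2")

  # unknown occasion: error listing valid labels
  bad2 <- df
  bad2$occasion[1] <- "brunch"
  readr::write_csv(bad2, path)
  expect_error(read_recalls(path, food_groups = groups4),
               "brunch.*breakfast")

  # duplicate keys are summed with a warning
  dup <- dplyr::bind_rows(long_row("P1", 1L, "breakfast", "Bread", 10),
                          long_row("P1", 1L, "breakfast", "Bread", 5))
  readr::write_csv(dup, path)
  expect_warning(rec2 <- read_recalls(path, food_groups = groups4),
                 "duplicate")
  expect_equal(rec2$grams, 15)

  # a raw-item map is total: unmapped items error rather than drop
  readr::write_csv(long_row("P1", 1L, "breakfast", "rye bread", 30), path)
  expect_error(read_recalls(path, group_map = c("white bread" = "Bread"),
                            food_groups = groups4),
               "rye bread")
  rec3 <- read_recalls(path, group_map = c("rye bread" = "Bread"),
                       food_groups = groups4)
  expect_equal(rec3$food_group, "Bread")
})

test_that("meal tables contain exactly the positive-intake occurrences", {
  df <- dplyr::bind_rows(
    long_row("P1", 1L, "breakfast", "Bread", 30),
    long_row("P1", 2L, "lunch", "Bread", 20),     # P1 skipped breakfast day 2
    long_row("P2", 1L, "breakfast", "Coffee", 200),
    long_row("P2", 1L, "breakfast", "Bread", 50),
    long_row("P3", 1L, "dinner", "Tea", 150)
  )
  rec <- recalls_from_df(df, groups4)
  bt <- build_meal_table(rec, "breakfast")
  expect_equal(nrow(bt), 2L)                       # P1 day1, P2 day1
  expect_identical(attr(bt, "food_groups"), groups4)
  expect_equal(ncol(intake_matrix(bt)), 4L)
  expect_equal(bt$Bread, c(30, 50))
  expect_equal(bt$Coffee, c(0, 200))               # zeros retained

  # meal with no positive occurrence anywhere: degenerate
  expect_error(build_meal_table(rec, "afternoon snack"), "Fewer than 2")
  expect_error(build_meal_table(rec, "brunch"), "Unknown occasion")
})

test_that("meal tables draw on disjoint source records and match a recount", {
  preset <- cohort_preset(n_participants = 25)
  rec <- generate_recalls(preset$cohort, preset$margins, seed = 9)
  long <- tibble::as_tibble(rec)
  total_by_meal <- long |>
    dplyr::filter(occasion %in% main_meals()) |>
    dplyr::group_by(occasion) |>
    dplyr::summarise(total = sum(grams), .groups = "drop")
  for (m in main_meals()) {
    mt <- build_meal_table(rec, m)
    # direct recount of recall-days with positive intake at this occasion
    expected_rows <- long |>
      dplyr::filter(occasion == m, grams > 0) |>
      dplyr::distinct(participant_id, recall_index) |>
      nrow()
    expect_equal(nrow(mt), expected_rows)
    # grams in this table come only from this occasion
    expect_equal(sum(intake_matrix(mt)),
                 total_by_meal$total[total_by_meal$occasion == m])
  }
})

test_that("habitual averaging sums occasions within days, averages days", {
  df <- dplyr::bind_rows(
    long_row("P1", 1L, "breakfast", "Bread", 30),
    long_row("P1", 1L, "dinner", "Bread", 40)
  )
  rec <- recalls_from_df(df, groups4)
  ht <- build_habitual_table(rec)
  expect_equal(ht$Bread, 70)

  df2 <- dplyr::bind_rows(
    long_row("P1", 1L, "breakfast", "Bread", 60),
    long_row("P1", 2L, "dinner", "Bread", 80)
  )
  ht2 <- build_habitual_table(recalls_from_df(df2, groups4))
  expect_equal(ht2$Bread, 70)
  expect_equal(ht2$n_recalls, 2L)

  # preset cohort: one row per participant
  preset <- cohort_preset(n_participants = 30)
  rec3 <- generate_recalls(preset$cohort, preset$margins, seed = 2)
  ht3 <- build_habitual_table(rec3)
  expect_equal(nrow(ht3), 30L)
})

test_that("habitual means equal a brute-force recomputation on random data", {
  for (s in 1:5) {
    df <- withr::with_seed(s, {
      n <- 40
      tibble::tibble(
        participant_id = sample(c("P1", "P2", "P3"), n, replace = TRUE),
        recall_index = sample(1:2, n, replace = TRUE),
        occasion = sample(default_occasions(), n, replace = TRUE),
        food_group = sample(groups4, n, replace = TRUE),
        grams = round(runif(n, 0.1, 100), 2)
      ) |> dplyr::distinct(participant_id, recall_index, occasion,
                            food_group, .keep_all = TRUE)
    })
    rec <- recalls_from_df(df, groups4)
    ht <- build_habitual_table(rec)
    for (pid in unique(df$participant_id)) {
      days <- unique(df$recall_index[df$participant_id == pid])
      for (g in groups4) {
        # mean over this participant's recall days of occasion-summed intake
        daily <- vapply(days, function(d) {
          sum(df$grams[df$participant_id == pid & df$recall_index == d &
                         df$food_group == g])
        }, numeric(1))
        expect_equal(ht[[g]][ht$participant_id == pid], mean(daily))
      }
    }
  }
})

test_that("summarize_intake reports mean and n-1 SD", {
  df <- dplyr::bind_rows(
    long_row("P1", 1L, "breakfast", "Bread", 10),
    long_row("P2", 1L, "breakfast", "Coffee", 100),
    long_row("P3", 1L, "breakfast", "Coffee", 100)
  )
  rec <- recalls_from_df(df, groups4)
  s <- summarize_intake(build_meal_table(rec, "breakfast"))
  # column {0, 0, 100+...}: bread column is {10, 0, 0}
  expect_equal(s$mean[s$food_group == "Bread"], 10 / 3)
  # constant-ish: tea never consumed -> mean 0, sd 0
  expect_equal(s$sd[s$food_group == "Tea"], 0)
  # two-point column {0, 10}: mean 5, sd sqrt(50)
  df2 <- dplyr::bind_rows(long_row("P1", 1L, "breakfast", "Bread", 10),
                          long_row("P2", 1L, "breakfast", "Coffee", 5))
  s2 <- summarize_intake(build_meal_table(recalls_from_df(df2, groups4),
                                          "breakfast"))
  expect_equal(s2$mean[s2$food_group == "Bread"], 5)
  expect_equal(s2$sd[s2$food_group == "Bread"], sqrt(50))

  empty <- build_meal_table(rec, "breakfast")[0, ]
  class(empty) <- class(build_meal_table(rec, "breakfast"))
  attr(empty, "food_groups") <- groups4
  expect_error(summarize_intake(empty), "Empty")
})
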