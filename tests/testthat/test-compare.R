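keyed <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(from = m[, 1], to = m[, 2], pcor = as.numeric(m[, 3]))
}

test_that("edge overlap matches pairs direction-specifically", {
  meal <- net_from_edges(keyed("A", "B", 0.4, "B", "C", -0.2, "C", "D", 0.3))
  hab <- net_from_edges(keyed("A", "B", 0.3, "B", "C", 0.25))
  ov <- edge_overlap(meal, hab)
  expect_equal(ov$n_matched, 1L)         # (B,C) excluded: sign flip
  expect_equal(ov$n_edges, 3L)
  expect_equal(ov$percentage, 33.3)

  # sign-agnostic mode counts the flipped pair too
  expect_equal(edge_overlap(meal, hab, sign_specific = FALSE)$percentage,
               66.7)

  expect_equal(edge_overlap(meal, meal)$percentage, 100.0)
  disj <- net_from_edges(keyed("P", "Q", 0.5, "Q", "R", 0.5))
  expect_equal(edge_overlap(meal, disj)$percentage, 0.0)

  # an edgeless network is an explicit empty marker, not 0%
  empty <- partial_correlations(diag(3) * 2)
  ov_e <- edge_overlap(empty, hab)
  expect_identical(ov_e$status, "empty")
  expect_true(is.na(ov_e$percentage))
})

test_that("only edges of >= 3-node components enter the comparison", {
  # one triangle plus an isolated dyad: the dyad edge must not count
  net <- net_from_edges(keyed("A", "B", 0.4, "B", "C", 0.4, "A", "C", 0.4,
                              "X", "Y", 0.9))
  expect_equal(nrow(network_edge_keys(net)), 3L)
  expect_equal(nrow(network_edge_keys(net, networks_only = FALSE)), 4L)
  # two >= 3-node components pool their edges
  net2 <- net_from_edges(keyed("A", "B", 0.4, "B", "C", 0.4,
                               "P", "Q", 0.4, "Q", "R", 0.4))
  expect_equal(nrow(network_edge_keys(net2)), 4L)
})

test_that("habitual-only percentage complements meal matching", {
  hab <- net_from_edges(keyed("A", "B", 0.4, "C", "D", -0.3, "B", "C", 0.2))
  meals <- list(b = net_from_edges(keyed("A", "B", 0.3, "B", "C", 0.2)))
  hu <- habitual_unique(hab, meals)
  expect_equal(hu$n_unique, 1L)          # (C,D,-) unmatched
  expect_equal(hu$percentage, 33.3)

  # habitual subset of the meal union: 0%
  hu0 <- habitual_unique(meals$b, list(hab = hab))
  expect_equal(hu0$percentage, 0)

  # meals all empty: 100%
  empty <- partial_correlations(diag(2) * 2)
  expect_equal(habitual_unique(hab, list(e = empty))$percentage, 100)
  expect_identical(habitual_unique(empty, meals)$status, "empty")
})

test_that("sign-discordant pairs are listed deterministically", {
  a <- net_from_edges(keyed("A", "B", 0.4, "B", "C", 0.3, "C", "D", 0.2))
  b <- net_from_edges(keyed("A", "B", 0.4, "B", "C", -0.3, "C", "D", 0.2))
  d <- sign_discordance(a, b)
  expect_equal(nrow(d), 1L)
  expect_equal(d$from, "B")
  expect_equal(d$pcor_net, 0.3)
  expect_equal(d$pcor_reference, -0.3)

  expect_equal(nrow(sign_discordance(a, a)), 0L)
  disj <- net_from_edges(keyed("P", "Q", 0.5, "Q", "R", 0.5))
  expect_equal(nrow(sign_discordance(a, disj)), 0L)
})

test_that("strength summaries report mean and max |pcor|", {
  one <- net_from_edges(keyed("A", "B", 0.5, "B", "C", 0.0001))
  two <- net_from_edges(keyed("A", "B", 0.2, "B", "C", -0.4))
  s <- strength_comparison(list(one = one, two = two))
  expect_equal(s$mean_abs_pcor[s$network == "two"], 0.3)
  expect_equal(s$max_abs_pcor[s$network == "two"], 0.4)
  empty <- partial_correlations(diag(2) * 2)
  s_e <- strength_comparison(list(e = empty))
  expect_identical(s_e$status, "empty")
  expect_true(is.na(s_e$mean_abs_pcor))
})

test_that("matched plus habitual-only percentages partition the habitual edges", {
  rand_net <- function(seed) {
    nodes <- LETTERS[1:8]
    withr::with_seed(seed, {
      pairs <- t(combn(nodes, 2))
      sel <- sample.int(nrow(pairs), 8)
      net_from_edges(data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                                pcor = round(runif(8, -0.5, 0.5), 2)))
    })
  }
  for (s in 1:100) {
    hab <- rand_net(s)
    meals <- list(m1 = rand_net(s + 1000), m2 = rand_net(s + 2000))
    hk <- network_edge_keys(hab)
    if (nrow(hk) == 0L) next
    hu <- habitual_unique(hab, meals)
    pooled <- dplyr::bind_rows(lapply(meals, network_edge_keys))
    matched <- sum(paste(hk$from, hk$to, hk$sign) %in%
                     paste(pooled$from, pooled$to, pooled$sign))
    expect_equal(hu$n_unique + matched, nrow(hk))
    expect_equal(hu$percentage + round(100 * matched / nrow(hk), 1), 100,
                 tolerance = 0.11)  # two independently rounded halves
  }
})

test_that("the overlap report round-trips through its exports", {
  meal <- net_from_edges(keyed("A", "B", 0.4, "B", "C", -0.2, "C", "D", 0.3))
  hab <- net_from_edges(keyed("A", "B", 0.3, "B", "C", 0.25))
  rep <- overlap_report(list(breakfast = meal), hab)
  expect_equal(rep$overlap$percentage, 33.3)
  expect_equal(nrow(rep$discordant), 1L)

  dir <- withr::local_tempdir()
  write_overlap_report(rep, file.path(dir, "cmp"))
  write_edge_list(meal, file.path(dir, "meal.tsv"))
  write_edge_list(hab, file.path(dir, "hab.tsv"))

  # recompute the percentage from the exported edge lists, independently
  me <- readr::read_tsv(file.path(dir, "meal.tsv"), show_col_types = FALSE)
  he <- readr::read_tsv(file.path(dir, "hab.tsv"), show_col_types = FALSE)
  key <- function(df) paste(pmin(df$source, df$target),
                            pmax(df$source, df$target), sign(df$pcor))
  pct <- round(100 * mean(key(me) %in% key(he)), 1)
  expect_equal(pct, 33.3)
  js <- jsonlite::read_json(file.path(dir, "cmp.json"), simplifyVector = TRUE)
  expect_equal(js$overlap$percentage, 33.3)
})

test_that("matched relations are stronger at meal level than habitually", {
  # the attenuation phenomenon, assessed pairwise: for node pairs carrying
  # an edge in both a meal network and the habitual network, the meal-level
  # partial correlation is on average the stronger one
  for (s in 1:2) {
    preset <- cohort_preset()
    rec <- generate_recalls(preset$cohort, preset$margins, seed = s)
    hab <- fit_dietary_network(build_habitual_table(rec), seed = s + 100)$network
    eh <- network_edge_keys(hab)
    diffs <- unlist(lapply(main_meals(), function(m) {
      net <- fit_dietary_network(build_meal_table(rec, m),
                                 seed = s + 100)$network
      e <- dplyr::inner_join(network_edge_keys(net), eh, by = c("from", "to"),
                             suffix = c(".meal", ".hab"))
      abs(e$pcor.meal) - abs(e$pcor.hab)
    }))
    expect_gt(length(diffs), 5L)
    expect_gt(mean(diffs), 0)
  }
})
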