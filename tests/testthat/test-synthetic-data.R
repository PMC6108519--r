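test_that("make_precision realizes requested partial correlations", {
  # empty graph: identity precision, all partial correlations zero
  empty <- graph_spec(4, "custom",
                      edges = data.frame(from = integer(), to = integer(),
                                         sign = integer()))
  om <- make_precision(empty)
  expect_equal(unclass(om), diag(4), ignore_attr = TRUE)

  # hub on 5 nodes: exactly 4 nonzero pairs, realized pcor in [0.25, 0.35],
  # checked through the inverse-covariance route (independent of attr)
  hub <- graph_spec(5, "hub", target_pcor = 0.3)
  om <- make_precision(hub)
  nz <- which(om != 0 & upper.tri(om), arr.ind = TRUE)
  expect_equal(nrow(nz), 4L)
  sigma <- solve(om)
  for (k in seq_len(nrow(nz))) {
    pc <- cond_pcor(sigma, nz[k, 1], nz[k, 2])
    expect_gte(pc, 0.25)
    expect_lte(pc, 0.35)
  }

  # signs carried through
  signed <- graph_spec(3, "custom",
                       edges = data.frame(from = c(1, 2), to = c(2, 3),
                                          sign = c(1, -1)),
                       target_pcor = 0.3)
  pc <- attr(make_precision(signed), "pcor")
  expect_gt(pc[1, 2], 0)
  expect_lt(pc[2, 3], 0)

  # extreme chain target: either a PD success or the infeasibility error
  res <- tryCatch(make_precision(graph_spec(3, "chain", target_pcor = 0.9)),
                  error = function(e) e)
  if (!inherits(res, "error")) {
    expect_gt(min(eigen(res, symmetric = TRUE, only.values = TRUE)$values), 0)
  } else {
    expect_match(conditionMessage(res), "0.9|infeasible|iterations")
  }
})

test_that("graph_spec validates its invariants", {
  expect_error(graph_spec(3, "custom",
                          edges = data.frame(from = 1, to = 1, sign = 1)),
               "Self-edges")
  expect_error(graph_spec(3, "custom",
                          edges = data.frame(from = c(1, 2), to = c(2, 1),
                                             sign = 1)),
               "Duplicate")
  expect_error(graph_spec(3, "hub", target_pcor = 1.2), "strictly between")
})

test_that("generated amounts follow the specified margins and copula", {
  groups <- sprintf("G%d", 1:4)
  # no zero inflation + empty graph: no zeros, near-zero Spearman
  marg0 <- margin_spec(groups, zero_probability = 0, par1 = log(30),
                       par2 = 0.6)
  empty <- graph_spec(4, "custom",
                      edges = data.frame(from = integer(), to = integer(),
                                         sign = integer()))
  X <- simulate_meal_matrix(empty, marg0, n = 500, seed = 3)
  expect_equal(sum(X == 0), 0L)
  R <- cor(X, method = "spearman")
  expect_lt(max(abs(R[upper.tri(R)])), 0.12)

  # heavy zero inflation: per-column zero fraction near 0.9
  marg9 <- margin_spec(groups, zero_probability = 0.9, par1 = log(30),
                       par2 = 0.6)
  X9 <- simulate_meal_matrix(empty, marg9, n = 2000, seed = 4)
  zf <- colMeans(X9 == 0)
  expect_true(all(zf >= 0.85 & zf <= 0.95))
})

test_that("monotone margins preserve the rank correlation (copula invariance)", {
  groups <- sprintf("G%d", 1:3)
  g <- graph_spec(3, "chain", target_pcor = 0.4)
  margA <- margin_spec(groups, zero_probability = 0, par1 = 0, par2 = 1)
  margB <- margin_spec(groups, zero_probability = 0, par1 = 3, par2 = 0.2)
  XA <- simulate_meal_matrix(g, margA, n = 5000, seed = 5)
  XB <- simulate_meal_matrix(g, margB, n = 5000, seed = 5)
  # identical seed, different monotone margins: identical rank correlations
  expect_equal(cor(XA, method = "spearman"), cor(XB, method = "spearman"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # and the skeptic estimate recovers the latent correlation
  latent <- stats::cov2cor(solve(make_precision(g)))
  Sk <- skeptic_correlation(XA)
  expect_lt(max(abs(unclass(Sk) - latent)), 0.05)
})

test_that("zero inflation attenuates but never flips Spearman correlation signs", {
  groups <- c("A", "B")
  for (sgn in c(1L, -1L)) {
    g <- graph_spec(2, "custom",
                    edges = data.frame(from = 1, to = 2, sign = sgn),
                    target_pcor = 0.45)
    m_full <- margin_spec(groups, zero_probability = 0, par1 = log(20),
                          par2 = 0.7)
    m_zero <- margin_spec(groups, zero_probability = 0.6, par1 = log(20),
                          par2 = 0.7)
    Xf <- simulate_meal_matrix(g, m_full, n = 10000, seed = 6)
    Xz <- simulate_meal_matrix(g, m_zero, n = 10000, seed = 6)
    rf <- cor(Xf[, 1], Xf[, 2], method = "spearman")
    rz <- cor(Xz[, 1], Xz[, 2], method = "spearman")
    expect_equal(sign(rz), sign(rf))
    expect_equal(sign(rf), sgn)
    expect_lt(abs(rz), abs(rf))   # one-sided attenuation
  }
})

test_that("the preset cohort matches its documented dimensions and moments", {
  preset <- cohort_preset()
  expect_length(preset$cohort$occasions, 11L)
  expect_length(preset$cohort$food_groups, 39L)
  expect_identical(preset$cohort$food_groups, meal_intake_moments()$food_group)
  expect_setequal(names(preset$cohort$meal_graphs), main_meals())
  # no latent relation is common to all four meals
  keys <- lapply(preset$cohort$meal_graphs,
                 function(g) paste(g$edges$from, g$edges$to))
  common <- Reduce(intersect, keys)
  expect_length(common, 0L)

  rec <- generate_recalls(preset$cohort, preset$margins, seed = 1)
  days <- dplyr::distinct(tibble::as_tibble(rec), participant_id, recall_index)
  expect_equal(nrow(days), 814L * 3L)
  for (m in main_meals()) {
    expect_lte(nrow(build_meal_table(rec, m)), 2442L)
  }
  # breakfast bread mean close to the calibration target (52.09 g)
  bt <- build_meal_table(rec, "breakfast")
  bread <- summarize_intake(bt) |> dplyr::filter(food_group == "Bread")
  expect_lt(abs(bread$mean - 52.09) / 52.09, 0.15)
})

test_that("generation is reproducible and round-trips through CSV", {
  preset <- cohort_preset(n_participants = 15)
  r1 <- generate_recalls(preset$cohort, preset$margins, seed = 42)
  r2 <- generate_recalls(preset$cohort, preset$margins, seed = 42)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  r3 <- generate_recalls(preset$cohort, preset$margins, seed = 43)
  expect_false(identical(tibble::as_tibble(r1), tibble::as_tibble(r3)))

  path <- withr::local_tempfile(fileext = ".csv")
  write_recalls(r1, path)
  r1b <- read_recalls(path)
  expect_equal(tibble::as_tibble(r1), tibble::as_tibble(r1b),
               tolerance = 1e-12)
  expect_identical(attr(r1b, "food_groups"), attr(r1, "food_groups"))
  expect_identical(attr(r1b, "seed"), 42L)
})

test_that("margins_from_moments reproduces target means and SDs", {
  m <- c(52.09, 0.01, 220.36)
  s <- c(33.41, 0.40, 170.34)
  spec <- margins_from_moments(c("a", "b", "c"), m, s)
  expect_true(all(spec$zero_probability < 1))
  # mixture moments implied by the calibrated margins
  mu_pos <- exp(spec$par1 + spec$par2^2 / 2)
  var_pos <- (exp(spec$par2^2) - 1) * mu_pos^2
  mean_mix <- (1 - spec$zero_probability) * mu_pos
  var_mix <- (1 - spec$zero_probability) * (var_pos + mu_pos^2) - mean_mix^2
  expect_equal(mean_mix, m, tolerance = 1e-8)
  expect_equal(sqrt(var_mix), s, tolerance = 1e-6)
})
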