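# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks.

# Proximal-gradient (ISTA with backtracking) solver for the glasso
# objective: minimize -logdet(Theta) + tr(S Theta) + lambda * ||Theta||_1.
# First-order method, structurally unrelated to block coordinate descent.
ista_glasso <- function(S, lambda, penalize_diagonal = TRUE,
                        max_iter = 50000L, tol = 1e-11) {
  p <- ncol(S)
  Lm <- matrix(lambda, p, p)
  if (!penalize_diagonal) diag(Lm) <- 0
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  fsmooth <- function(Th) {
    ch <- tryCatch(chol(Th), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    -2 * sum(log(diag(ch))) + sum(S * Th)
  }
  Th <- diag(1 / diag(S))
  f_old <- fsmooth(Th) + sum(Lm * abs(Th))
  eta <- 1
  for (it in seq_len(max_iter)) {
    G <- S - solve(Th)
    repeat {
      cand <- soft(Th - eta * G, eta * Lm)
      cand <- 0.5 * (cand + t(cand))
      fs <- fsmooth(cand)
      ok <- is.finite(fs) &&
        fs <= fsmooth(Th) + sum(G * (cand - Th)) +
          sum((cand - Th)^2) / (2 * eta)
      if (ok) break
      eta <- eta / 2
      if (eta < 1e-12) break
    }
    f_new <- fs + sum(Lm * abs(cand))
    delta <- max(abs(cand - Th))
    Th <- cand
    if (abs(f_old - f_new) < tol && delta < 1e-9) break
    f_old <- f_new
    eta <- min(eta * 2, 1)
  }
  Th
}

# Partial correlation via the conditional (Schur-complement) covariance of
# (i, j) given the rest - the regress-residual identity, avoiding the
# -omega_ij / sqrt(omega_ii omega_jj) formula entirely.
cond_pcor <- function(Sigma, i, j) {
  rest <- setdiff(seq_len(ncol(Sigma)), c(i, j))
  if (length(rest) == 0L) {
    return(Sigma[i, j] / sqrt(Sigma[i, i] * Sigma[j, j]))
  }
  A <- Sigma[c(i, j), c(i, j)]
  B <- Sigma[c(i, j), rest, drop = FALSE]
  C <- Sigma[rest, rest, drop = FALSE]
  V <- A - B %*% solve(C, t(B))
  V[1, 2] / sqrt(V[1, 1] * V[2, 2])
}

# Kendall tau-b by exhaustive pair enumeration with tie corrections.
tau_b_enum <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      s <- sign(x[a] - x[b]) * sign(y[a] - y[b])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Edge-set F1 between an estimated precision support and a true edge list.
edge_f1 <- function(omega, true_edges) {
  est <- which(omega != 0 & upper.tri(omega), arr.ind = TRUE)
  estk <- paste(est[, 1], est[, 2])
  truth <- paste(pmin(true_edges$from, true_edges$to),
                 pmax(true_edges$from, true_edges$to))
  tp <- sum(estk %in% truth)
  if (length(estk) == 0L || tp == 0L) return(0)
  prec <- tp / length(estk)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}

# Seeded random connected graph with n_edges edges on n_nodes labels.
random_connected_graph <- function(n_nodes, n_edges, seed) {
  withr::with_seed(seed, {
    repeat {
      pairs <- t(combn(n_nodes, 2))
      sel <- sample.int(nrow(pairs), n_edges)
      e <- data.frame(from = letters[pairs[sel, 1]], to = letters[pairs[sel, 2]])
      g <- igraph::graph_from_data_frame(e, directed = FALSE)
      if (igraph::is_connected(g) &&
          igraph::vcount(g) == length(unique(c(e$from, e$to)))) {
        return(e)
      }
    }
  })
}

# pcor_network from a bare signed edge list (pcor values given directly).
net_from_edges <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  p <- length(nodes)
  om <- diag(1, p)
  dimnames(om) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    om[edges$from[i], edges$to[i]] <- -edges$pcor[i]
    om[edges$to[i], edges$from[i]] <- -edges$pcor[i]
  }
  partial_correlations(om, labels = nodes)
}

# Recall dataset from a long data frame, via the CSV reader (exercises IO).
recalls_from_df <- function(df, food_groups, occasions = default_occasions(),
                            meals = main_meals()) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  read_recalls(path, food_groups = food_groups, occasions = occasions,
               meals = meals)
}
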