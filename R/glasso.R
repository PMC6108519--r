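#' Graphical lasso fit at a fixed penalty
#'
#' Maximizes `log det(Omega) - tr(S Omega) - lambda * ||Omega||_1` by block
#' coordinate descent (compiled). By default the penalty covers the
#' diagonal (the classic glasso convention, under which
#' `lambda >= max|s_ij|` yields the exactly diagonal solution
#' `omega_ii = 1/(s_ii + lambda)`); set `penalize_diagonal = FALSE` for the
#' off-diagonal-only variant. The returned fit carries the Karush-Kuhn-
#' Tucker residual — the contract is the KKT condition, not the solver:
#' `|sigma_hat_ij - s_ij| <= lambda` for every off-diagonal pair, with
#' equality at `lambda` and sign consistency wherever `omega_ij != 0`.
#'
#' @param S Covariance/correlation input (e.g. a `skeptic_correlation`).
#' @param lambda Penalty, `> 0`.
#' @param penalize_diagonal Include diagonal entries in the penalty?
#' @param max_iter,tol Outer sweep limit and relative convergence tolerance.
#' @param kkt_tol Maximum admissible KKT residual; exceeding it after
#'   `max_iter` sweeps is a convergence error.
#' @param penalty_matrix Optional symmetric matrix of entrywise penalties
#'   overriding the scalar (used e.g. for support-constrained refits).
#' @param inner_max_iter Iteration budget per column of the inner lasso
#'   coordinate descent (lower it for cheap approximate fits).
#' @return Object of class `glasso_fit`: `omega`, `sigma` (the exact
#'   inverse of `omega`), `lambda`, `objective`, `kkt_residual`,
#'   `iterations`, `labels`.
#' @export
glasso_fit <- function(S, lambda, penalize_diagonal = TRUE,
                       max_iter = 500L, tol = 1e-7, kkt_tol = 1e-5,
                       penalty_matrix = NULL, inner_max_iter = 2000L) {
  labels <- colnames(S)
  Sm <- unclass(S)
  attributes(Sm) <- attributes(Sm)["dim"]
  p <- ncol(Sm)
  if (is.null(penalty_matrix)) {
    if (lambda <= 0) abort("`lambda` must be positive.")
    Lm <- matrix(lambda, p, p)
    if (!penalize_diagonal) diag(Lm) <- 0
  } else {
    Lm <- penalty_matrix
    stopifnot(all(dim(Lm) == p), isSymmetric(unname(Lm)), all(Lm >= 0))
  }
  res <- glasso_cpp(Sm, Lm, as.integer(max_iter), tol,
                    as.integer(inner_max_iter), tol)
  omega <- res$theta
  sigma <- solve(omega)
  kkt <- kkt_residual(Sm, omega, sigma, Lm)
  if (kkt > kkt_tol) {
    abort(sprintf(
      "glasso did not converge: KKT residual %.2e > %.0e after %d sweeps.",
      kkt, kkt_tol, res$iterations))
  }
  obj <- determinant(omega, logarithm = TRUE)$modulus[1] -
    sum(Sm * omega) - sum(Lm * abs(omega))
  dimnames(omega) <- dimnames(sigma) <- list(labels, labels)
  structure(
    list(omega = omega, sigma = sigma, lambda = lambda,
         penalize_diagonal = penalize_diagonal, objective = as.numeric(obj),
         kkt_residual = kkt, iterations = res$iterations, labels = labels),
    class = "glasso_fit"
  )
}

# max violation of the stationarity conditions of the penalized likelihood;
# entries under an effectively infinite penalty (hard zeros) are exempt
kkt_residual <- function(S, omega, sigma, Lm) {
  G <- sigma - S   # should equal Lambda * subgradient(|omega|)
  free <- Lm < 1e5
  on_support <- free & omega != 0 & row(G) != col(G)
  off_support <- free & omega == 0
  r <- 0
  if (any(on_support)) {
    r <- max(r, max(abs(G[on_support] - Lm[on_support] * sign(omega[on_support]))))
  }
  if (any(off_support)) {
    r <- max(r, max(pmax(0, abs(G[off_support]) - Lm[off_support])))
  }
  r <- max(r, max(abs(diag(G) - diag(Lm))))  # omega_ii > 0 always
  r
}

#' Support-constrained maximum-likelihood refit
#'
#' Unpenalized Gaussian MLE of the precision matrix restricted to a given
#' edge support (plus the diagonal): off-support entries are forced to
#' exact zero via an effectively infinite entrywise penalty. Used to
#' remove lasso shrinkage from selected models: on-support entries then
#' satisfy `sigma_hat_ij = s_ij` exactly.
#'
#' @param S Correlation input.
#' @param support Logical/0-1 symmetric matrix (or a `glasso_fit`, whose
#'   nonzero pattern is used).
#' @inheritParams glasso_fit
#' @return A `glasso_fit` (with `lambda = 0`).
#' @export
refit_support <- function(S, support, max_iter = 500L, tol = 1e-7,
                          kkt_tol = 1e-5, inner_max_iter = 2000L) {
  if (inherits(support, "glasso_fit")) support <- support$omega != 0
  p <- ncol(S)
  stopifnot(all(dim(support) == p))
  Lm <- matrix(1e9, p, p)
  Lm[support != 0] <- 0
  diag(Lm) <- 0
  glasso_fit(S, lambda = 0, penalty_matrix = Lm, max_iter = max_iter,
             tol = tol, kkt_tol = kkt_tol, inner_max_iter = inner_max_iter)
}

#' Penalty grid for the glasso path
#'
#' 30 log-spaced values descending from `lambda_max = max off-diagonal
#' |s_ij|` (above which the graph is empty) down to
#' `lambda_min_ratio * lambda_max`.
#'
#' @param S Correlation input.
#' @param nlambda Grid length.
#' @param lambda_min_ratio Smallest-to-largest ratio.
#' @return Strictly decreasing numeric vector.
#' @export
lambda_grid <- function(S, nlambda = 30L, lambda_min_ratio = 0.01) {
  lmax <- max(abs(S[row(S) != col(S)]))
  lmax <- max(lmax, 1e-4)
  exp(seq(log(lmax), log(lambda_min_ratio * lmax), length.out = nlambda))
}

#' Tenfold cross-validated penalty selection
#'
#' Rows are shuffled (seeded) into `k` folds. For each fold the skeptic
#' correlation matrix is re-estimated on the training rows and a glasso
#' path is fit over the common grid. The held-out Gaussian negative
#' log-likelihood `tr(S_test Omega) - log det Omega` is evaluated on the
#' skeptic matrix of the held-out rows — by default (`refit = TRUE`) on
#' the support-constrained MLE refit of each path model
#' ([refit_support()]), so the selection scores each penalty's *edge set*
#' rather than its shrunken coefficients; scoring the shrunken estimates
#' themselves (`refit = FALSE`) systematically drags the minimum toward
#' dense graphs. The selected `lambda*` minimizes the mean held-out loss;
#' exact ties break toward the larger (sparser) penalty. Constant columns
#' within a fold are flagged by the skeptic step and the loss is computed
#' on the PSD-corrected matrix.
#'
#' @param x Observation matrix or analysis table.
#' @param method Rank-correlation method.
#' @param lambda Optional penalty grid (positive, descending); default
#'   [lambda_grid()] on the full-data skeptic matrix.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle.
#' @param refit Score support refits (default) or penalized estimates?
#' @param nlambda,lambda_min_ratio Grid parameters when `lambda` is NULL.
#' @return Object of class `cv_glasso`: tibble `path` (lambda,
#'   mean_loss), `lambda_opt`, `fold_losses` matrix, `k`, `seed`,
#'   `method`, `refit`.
#' @export
cv_select_lambda <- function(x, method = c("spearman", "kendall"),
                             lambda = NULL, k = 10L, seed = 1L,
                             refit = TRUE, nlambda = 30L,
                             lambda_min_ratio = 0.01) {
  method <- match.arg(method)
  m <- if (is.matrix(x)) x else intake_matrix(x)
  n <- nrow(m)
  if (k > n) abort(sprintf("k = %d folds exceed n = %d observations.", k, n))
  S_full <- skeptic_correlation(m, method)
  if (is.null(lambda)) {
    lambda <- lambda_grid(S_full, nlambda, lambda_min_ratio)
  }
  if (any(diff(lambda) >= 0) || any(lambda <= 0)) {
    abort("`lambda` must be positive and strictly decreasing.")
  }

  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  loss <- matrix(NA_real_, k, length(lambda))
  for (f in seq_len(k)) {
    test <- folds == f
    S_tr <- skeptic_correlation(m[!test, , drop = FALSE], method)
    S_te <- skeptic_correlation(m[test, , drop = FALSE], method)
    prev_support <- NULL
    for (li in seq_along(lambda)) {
      fit <- glasso_fit(S_tr, lambda[li])
      omega <- fit$omega
      if (refit) {
        support <- omega != 0
        # supports repeat along the path; reuse the previous refit
        if (!is.null(prev_support) && identical(support, prev_support$support)) {
          omega <- prev_support$omega
        } else {
          # scoring tolerates partial convergence; near-singular training
          # matrices (eigenvalue-floored, dense supports) get a bounded
          # effort, and on failure the penalized estimate is scored
          rf <- tryCatch(refit_support(S_tr, support, max_iter = 100L,
                                       tol = 1e-6, kkt_tol = Inf,
                                       inner_max_iter = 50L),
                         error = function(e) NULL)
          if (!is.null(rf)) omega <- rf$omega
          prev_support <- list(support = support, omega = omega)
        }
      }
      loss[f, li] <- sum(S_te * omega) -
        determinant(omega, logarithm = TRUE)$modulus[1]
    }
  }
  mean_loss <- colMeans(loss)
  best <- which(mean_loss <= min(mean_loss) + 1e-12)[1L]  # grid descending: first = sparsest
  path <- tibble(lambda = lambda, mean_loss = mean_loss)
  structure(
    list(path = path, lambda_opt = lambda[best], fold_losses = loss,
         k = k, seed = seed, method = method, refit = refit),
    class = "cv_glasso"
  )
}

#' Fit the full network estimator to one analysis table
#'
#' The whole copula-graph stage in one call: skeptic correlation,
#' cross-validated penalty selection, glasso refit on the full data at
#' `lambda*`, and partial-correlation network extraction.
#'
#' @inheritParams cv_select_lambda
#' @param ... Passed to [cv_select_lambda()].
#' @return Object of class `dietary_network_fit`: list with `network`
#'   (a [partial_correlations()] result), `fit` (`glasso_fit`), `cv`
#'   (`cv_glasso`), `skeptic` (`skeptic_correlation`), and `label`.
#' @examples
#' preset <- cohort_preset(n_participants = 60)
#' rec <- generate_recalls(preset$cohort, preset$margins, seed = 7)
#' fit <- fit_dietary_network(build_meal_table(rec, "breakfast"), seed = 7)
#' glance(fit$network)
#' @export
fit_dietary_network <- function(x, method = c("spearman", "kendall"),
                                k = 10L, seed = 1L, ...) {
  method <- match.arg(method)
  label <- attr(x, "meal") %||% "habitual"
  m <- if (is.matrix(x)) x else intake_matrix(x)
  cv <- cv_select_lambda(m, method, k = k, seed = seed, ...)
  S <- skeptic_correlation(m, method)
  fit <- glasso_fit(S, cv$lambda_opt)
  if (cv$refit) {
    fit <- tryCatch(refit_support(S, fit), error = function(e) {
      warn(paste0("Support refit did not converge (",
                  conditionMessage(e), "); reporting the penalized fit."))
      fit
    })
  }
  net <- partial_correlations(fit)
  structure(list(network = net, fit = fit, cv = cv, skeptic = S,
                 label = label),
            class = "dietary_network_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
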