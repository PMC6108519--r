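#' Rank-correlation matrix with tie handling
#'
#' Spearman's rho on mid-ranks or Kendall's tau-b — both tie-adjusted,
#' which matters here because meal-level gram amounts are heavily
#' zero-inflated. Columns with zero variance (a food never eaten at that
#' meal) cannot carry rank information: they get correlation 0 with every
#' other column and are flagged in the `"constant_columns"` attribute so
#' they survive as isolated nodes rather than being dropped.
#'
#' @param x Observation matrix or a `meal_table`/`habitual_table`.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @return Symmetric correlation matrix with unit diagonal and attributes
#'   `"method"`, `"n_obs"`, `"constant_columns"`.
#' @export
rank_correlation_matrix <- function(x, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  m <- if (is.matrix(x)) x else intake_matrix(x)
  if (nrow(m) < 2L) abort("Need at least 2 observations.")
  const <- apply(m, 2L, function(v) length(unique(v)) == 1L)
  if (all(const)) abort("All columns are constant; no correlation estimable.")
  R <- diag(1, ncol(m))
  dimnames(R) <- list(colnames(m), colnames(m))
  live <- which(!const)
  R[live, live] <- cor(m[, live, drop = FALSE], method = method)
  diag(R) <- 1
  structure(R, method = method, n_obs = nrow(m),
            constant_columns = colnames(m)[const])
}

#' Nonparanormal skeptic transform of a rank-correlation matrix
#'
#' Converts rank correlations into estimates of the latent Gaussian
#' correlation via the sine maps `2*sin(pi*rho/6)` (Spearman) or
#' `sin(pi*tau/2)` (Kendall). The mapped matrix is not guaranteed positive
#' semidefinite, so eigenvalue clipping ([nearest_psd_correlation()]) is
#' applied when the smallest eigenvalue falls below `eigen_floor`.
#'
#' @param R Raw rank-correlation matrix from [rank_correlation_matrix()]
#'   (its `"method"` attribute is used unless `method` is given).
#' @param method `"spearman"` or `"kendall"`.
#' @param eigen_floor Smallest admissible eigenvalue after correction.
#' @param psd_correct Apply the correction when needed? Set `FALSE` to get
#'   the raw sine-mapped matrix (e.g. to inspect the closed-form values
#'   for singular inputs such as a perfectly correlated pair).
#' @return A `skeptic_correlation` matrix with attributes `method`,
#'   `n_obs`, `psd_corrected`, `min_eigenvalue_before_correction`,
#'   `constant_columns`.
#' @export
skeptic_transform <- function(R, method = NULL, eigen_floor = 1e-4,
                              psd_correct = TRUE) {
  if (is.null(method)) method <- attr(R, "method")
  if (is.null(method)) abort("Supply `method` (\"spearman\" or \"kendall\").")
  S <- switch(method,
    spearman = 2 * sin(pi * R / 6),
    kendall = sin(pi * R / 2),
    abort("`method` must be \"spearman\" or \"kendall\".")
  )
  diag(S) <- 1
  S <- 0.5 * (S + t(S))
  min_eig <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  corrected <- psd_correct && min_eig < eigen_floor
  if (corrected) S <- nearest_psd_correlation(S, eigen_floor)
  structure(S, method = method, n_obs = attr(R, "n_obs"),
            psd_corrected = corrected,
            min_eigenvalue_before_correction = min_eig,
            constant_columns = attr(R, "constant_columns"),
            class = c("skeptic_correlation", "matrix", "array"))
}

#' Eigenvalue-clipped positive-definite correlation repair
#'
#' Clips eigenvalues at `floor`, reassembles, and rescales to unit
#' diagonal. Matrices already meeting the floor are returned unchanged.
#'
#' @param S Symmetric matrix.
#' @param floor Eigenvalue floor (default 1e-4).
#' @return Corrected correlation matrix.
#' @export
nearest_psd_correlation <- function(S, floor = 1e-4) {
  out <- S
  # the unit-diagonal rescale can push eigenvalues back under the floor,
  # so clip-and-rescale is iterated (converges in a handful of rounds)
  for (it in 1:100) {
    e <- eigen(out, symmetric = TRUE)
    if (min(e$values) >= floor) break
    vals <- pmax(e$values, floor * 1.05)
    out <- e$vectors %*% (vals * t(e$vectors))
    d <- 1 / sqrt(diag(out))
    out <- out * outer(d, d)
    diag(out) <- 1
    out <- 0.5 * (out + t(out))
  }
  dimnames(out) <- dimnames(S)
  out
}

#' One-call skeptic correlation from observations
#'
#' Convenience wrapper: [rank_correlation_matrix()] then
#' [skeptic_transform()].
#'
#' @inheritParams rank_correlation_matrix
#' @inheritParams skeptic_transform
#' @return A `skeptic_correlation` matrix.
#' @export
skeptic_correlation <- function(x, method = c("spearman", "kendall"),
                                eigen_floor = 1e-4) {
  method <- match.arg(method)
  skeptic_transform(rank_correlation_matrix(x, method), method, eigen_floor)
}
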