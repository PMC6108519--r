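#' Marginal intake distributions for the simulator
#'
#' A `margin_spec` describes, per food group, the zero-inflated right-skewed
#' distribution of gram amounts at a single eating occasion: a point mass at
#' zero (`zero_probability`) plus a lognormal or gamma positive part. The
#' generator draws a latent Gaussian copula vector and maps each coordinate
#' through the marginal quantile function, so the dependence structure lives
#' entirely in the copula while the margins control skew and zero mass.
#'
#' @param food_groups Character vector of group names.
#' @param zero_probability Per-group probability of a zero amount, each in
#'   `[0, 1)`; recycled if scalar.
#' @param family `"lognormal"` (default) or `"gamma"`; recycled.
#' @param par1,par2 Positive-part parameters, recycled: `meanlog`/`sdlog`
#'   for lognormal, `shape`/`rate` for gamma. Must give finite mean and
#'   variance (gamma always does; lognormal needs finite `sdlog`).
#'
#' @return A tibble of class `margin_spec` with one row per food group.
#' @export
margin_spec <- function(food_groups, zero_probability = 0, family = "lognormal",
                        par1 = 0, par2 = 1) {
  n <- length(food_groups)
  out <- tibble(
    food_group = as.character(food_groups),
    zero_probability = rep_len(zero_probability, n),
    family = rep_len(family, n),
    par1 = rep_len(par1, n),
    par2 = rep_len(par2, n)
  )
  if (any(out$zero_probability < 0 | out$zero_probability >= 1)) {
    abort("`zero_probability` must lie in [0, 1) for every food group.")
  }
  if (!all(out$family %in% c("lognormal", "gamma"))) {
    abort("`family` must be \"lognormal\" or \"gamma\".")
  }
  if (any(!is.finite(out$par1)) || any(!is.finite(out$par2)) ||
      any(out$par2 <= 0)) {
    abort("Positive-part parameters must be finite with `par2` > 0.")
  }
  class(out) <- c("margin_spec", class(out))
  out
}

#' Calibrate zero-inflated lognormal margins to target means and SDs
#'
#' Given observed per-group meal-level means and standard deviations (as
#' printed in descriptive intake tables), solves for a zero probability and
#' lognormal positive part that reproduce both moments exactly. The split
#' between zero mass and positive-part spread is identified by fixing the
#' positive-part coefficient of variation at `cv_positive` when the data are
#' skewed enough (`sd >= cv_positive * mean`); otherwise the zero probability
#' is set to `min_zero` and the positive-part variance absorbs the rest.
#' Groups reported as 0 +/- 0 get `zero_probability = 0.99` with a ~1 g
#' positive part (a zero probability of exactly 1 is disallowed).
#'
#' @param food_groups,mean,sd Equal-length vectors of group names and target
#'   moments (grams per occasion).
#' @param cv_positive Assumed coefficient of variation of the positive part
#'   for heavily zero-inflated groups.
#' @param min_zero Zero probability floor for rarely-skipped groups.
#' @param max_zero Cap on the solved zero probability.
#' @return A [margin_spec()].
#' @export
margins_from_moments <- function(food_groups, mean, sd, cv_positive = 1.2,
                                 min_zero = 0.02, max_zero = 0.98) {
  stopifnot(length(food_groups) == length(mean), length(mean) == length(sd))
  n <- length(mean)
  pi0 <- numeric(n); mu <- numeric(n); sig <- numeric(n)
  for (i in seq_len(n)) {
    m <- mean[i]; s <- sd[i]
    if (m <= 0) {
      pi0[i] <- 0.99; mu[i] <- 1; sig[i] <- 0.5
    } else {
      if (s >= cv_positive * m) {
        mup <- (s^2 + m^2) / (m * (1 + cv_positive^2))
        p0 <- 1 - m / mup
        if (p0 > max_zero) p0 <- max_zero
        if (p0 < min_zero) p0 <- min_zero
      } else {
        p0 <- min_zero
      }
      mup <- m / (1 - p0)
      varp <- (s^2 + m^2) / (1 - p0) - mup^2
      if (varp <= 0) varp <- (0.2 * mup)^2
      pi0[i] <- p0; mu[i] <- mup; sig[i] <- sqrt(varp)
    }
  }
  sdlog2 <- log(1 + (sig / mu)^2)
  margin_spec(food_groups,
              zero_probability = pi0,
              family = "lognormal",
              par1 = log(mu) - sdlog2 / 2,
              par2 = sqrt(sdlog2))
}

# quantile of the positive part, vectorized over rows of a margin_spec
positive_quantile <- function(margins, u) {
  ifelse(margins$family == "lognormal",
         qlnorm(u, meanlog = margins$par1, sdlog = margins$par2),
         qgamma(u, shape = margins$par1, rate = margins$par2))
}

# map latent standard-normal draws to zero-inflated amounts
latent_to_amount <- function(z, margins) {
  u <- pnorm(z)
  pi0 <- margins$zero_probability
  amt <- numeric(length(z))
  pos <- u >= pi0
  if (any(pos)) {
    v <- (u[pos] - pi0[pos]) / (1 - pi0[pos])
    v <- pmin(v, 1 - 1e-12)
    amt[pos] <- positive_quantile(margins[pos, , drop = FALSE], v)
  }
  amt
}
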