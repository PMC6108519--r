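---
title: "Meal-level and habitual dietary networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meal-level and habitual dietary networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mealnets)
```

## The model

Dietary recall data record, per participant and recall day, the grams of
each of 39 food groups consumed at each of 11 eating occasions. Food
intake amounts are heavily zero-inflated and right-skewed, so an ordinary
Gaussian graphical model (GGM) — edges defined by nonzero partial
correlations $\rho_{jk\cdot rest} = -\omega_{jk}/\sqrt{\omega_{jj}\omega_{kk}}$
of a precision matrix $\Omega = \Sigma^{-1}$ — is not directly
applicable. mealnets therefore fits a *semiparametric Gaussian copula*
GGM: the observed amounts are assumed to be monotone transforms of a
latent Gaussian vector, and the latent correlation matrix is estimated
from ranks via the sine ("skeptic") maps

$$\hat S_{jk} = 2\sin\!\left(\frac{\pi}{6}\hat\rho_{jk}\right)
  \quad\text{(Spearman)},\qquad
  \hat S_{jk} = \sin\!\left(\frac{\pi}{2}\hat\tau_{jk}\right)
  \quad\text{(Kendall)},$$

which are consistent for the latent Gaussian correlation without any
distributional assumption on the margins. Spearman with mid-ranks is the
default (cheaper at thousands of observations); Kendall's tau-b is
available via `method = "kendall"`. Both handle the massive ties produced
by zero amounts.

A sparse precision matrix is then estimated by the graphical lasso,

$$\hat\Omega_\lambda = \arg\max_{\Omega \succ 0}\;
  \log\det\Omega - \mathrm{tr}(\hat S\,\Omega) - \lambda\|\Omega\|_1,$$

solved by block coordinate descent in compiled code. The penalty covers
the diagonal by default (the classic convention, under which
$\lambda \ge \max_{j\ne k}|\hat s_{jk}|$ gives the exactly diagonal
solution $\hat\omega_{jj} = 1/(\hat s_{jj}+\lambda)$);
`penalize_diagonal = FALSE` selects the off-diagonal-only variant. The
solver's contract is the KKT condition — every fit reports its maximal
stationarity violation and errors beyond `kkt_tol` — so any conforming
solver is exchangeable with this one.

Edges are the exact-zero support of $\hat\Omega$ (tolerance `1e-8`), not
a thresholded correlation: the model decides sparsity, not an arbitrary
cutoff. Partial correlations of magnitude at least 0.30 are flagged
*strong* (boundary inclusive), and connected components spanning at
least three food groups are the reported *networks*; isolated dyads are
kept but not counted as networks.

## Penalty selection by cross-validated refits

$\lambda$ is chosen on a 30-point log-spaced grid from
$\lambda_{\max} = \max_{j \neq k}|\hat s_{jk}|$ down to
$0.01\,\lambda_{\max}$ by tenfold cross-validation: rows are shuffled
with a fixed seed, the skeptic matrix is re-estimated per training fold
(the statistically correct reading; re-using the full-data matrix leaks
the held-out rows), and the held-out Gaussian negative log-likelihood
$\mathrm{tr}(\hat S_{test}\Omega) - \log\det\Omega$ is minimized, with
ties broken toward the sparser penalty.

One design choice here was genuinely open and we resolved it
empirically: *what* to score with the held-out loss. Scoring the
penalized estimates themselves systematically drags the minimum into the
dense regime — the lasso's shrinkage bias means a smaller $\lambda$
always buys a slightly better held-out likelihood long after the true
edges are exhausted, a well-documented property of likelihood-CV for the
graphical lasso (the one-standard-error heuristic only partly
compensates). mealnets therefore scores each penalty's *edge set*: the
path model's support is refit by support-constrained maximum likelihood
(off-support entries forced to exact zero via an effectively infinite
entrywise penalty) and the refit is evaluated on the held-out fold. This
"relaxed" or refitted CV removes shrinkage bias from selection while
remaining tenfold cross-validated glasso; with it, the selector leaves
independent columns nearly edge-free and recovers planted sparse
structures with high F1 (both verified in the test suite). The final
reported network is likewise the support-constrained MLE at
$\lambda^\*$, consistent with what the CV scored; `refit = FALSE`
restores plain penalized scoring and shrunken coefficients.

During CV scoring the refits run under a bounded iteration budget and
fall back to the penalized estimate if they fail (near-singular training
matrices on tiny folds); the final refit is computed at full tolerance.

## The synthetic cohort

The study population this package targets is not deposited, so the
generator is a first-class module: every downstream stage is validated
against data with known dependence structure.

* **Latent graphs.** `graph_spec()` + `make_precision()` build a
  positive-definite precision matrix whose support is a requested edge
  list and whose partial correlations hit a target magnitude within
  0.005, by diagonal-dominant initialization
  ($\omega_{jj} = 1 + \sum_k|\omega_{jk}| + 0.01$) and multiplicative
  rescaling of edge weights. Infeasible requests fail loudly: a degree-$d$
  hub cannot exceed $|\rho| = 1/\sqrt d$ for any PD precision, which is
  why the structure-recovery checks tile four 5-node stars to reach
  $p = 20$ at $|\rho| = 0.35$ rather than using a single 19-leaf star.
* **Margins.** Amounts are zero-inflated lognormal (gamma optional):
  the latent normal is thresholded at the zero probability and mapped
  through the positive-part quantile function above it. Thresholding the
  *latent* variable keeps the copula interpretable — a hurdle applied at
  random would destroy the dependence the estimator targets — and makes
  zero-inflation attenuation one-sided (it never flips a sign, verified
  as a property test). `margins_from_moments()` calibrates the zero mass
  and lognormal parameters to reproduce published meal-level means and
  SDs exactly; the split between zero mass and positive-part spread is
  identified by fixing the positive-part coefficient of variation at 1.2
  for heavily skewed groups (SD ≥ 1.2 × mean) and flooring the zero
  probability at 0.02 otherwise. Groups reported as 0 ± 0 at a meal get
  zero probability 0.99 with a ~1 g positive part.
* **Cohort structure.** The preset (`cohort_preset()`) has 814
  participants with three recall days each (2,442 recall days), 39 food
  groups, and 11 occasions of which breakfast, lunch, afternoon snack
  and dinner carry structured dependence. Day-to-day within-person
  correlation enters as a shared latent fraction,
  $z = \sqrt\rho\,u_{participant} + \sqrt{1-\rho}\,v_{day}$ with
  $\rho = s^2/(1+s^2)$ and default $s = 1$ ($\rho = 0.5$): the
  meal-level copula stays exactly the specified one and habitual
  averaging mixes rather than inflates it. No within-person correlation
  estimate exists for the cohort, so $s$ is an exposed free parameter, a
  modelling knob rather than a cohort claim.
* **Meal graphs differ by meal.** Each of the six meal pairs shares four
  edges (same sign in both meals) and each meal carries twelve private
  edges; no relation is common to all four meals. An earlier design with
  one core shared identically by all meals was discarded: its
  covariances add coherently in the occasion-summed habitual amounts,
  *reinforcing* habitual edges — the opposite of what partially shared
  meal structures (and observed meal networks) produce.
* **Non-meal occasions** receive independent low-level noise (95% zeros,
  median ~10 g), emulating unstructured small snacks so habitual
  averaging mixes structured and unstructured intake.

What the generator does **not** emulate: interviewer and portion-coding
effects, weekday/weekend structure, energy correlation between groups,
and any marginal dependence beyond the single latent graph per meal.
Passing tests therefore demonstrate that the estimator recovers known
copula structure under realistic margins and sample sizes — not that the
original cohort's specific networks are reproduced, which would require
the undeposited data.

## Tables from recalls

A *meal observation* is a recall day with positive total intake at that
occasion — the paper-style observation counts are below the recall count
because meals are skipped; the positive-total rule (beverages included)
is our operationalization, since no published rule exists. Habitual
intake sums all 11 occasions within each recall day and averages a
participant's available days with equal weights (no weekday weighting).
Food groups never consumed at a meal remain as all-zero columns: they
carry no rank information and are flagged, entering the model as
isolated nodes so node sets match across meals. Descriptive summaries
use the $n-1$ SD denominator.

## Link communities and centrality

Communities are communities of *edges*: the similarity of two edges
sharing node $k$, $(i,k)$ and $(j,k)$, is the Jaccard index of the
inclusive neighborhoods $n^+(i)$ and $n^+(j)$; non-adjacent edges have
similarity 0. Single-linkage agglomeration builds the dendrogram — every
cut equals the connected components of the thresholded edge-similarity
graph, which makes partitions robust to merge-order ties — and the cut
is chosen to maximize the partition density

$$D = \frac{2}{M}\sum_c m_c\,
  \frac{m_c - n_c + 1}{(n_c - 2)(n_c - 1)},$$

with $D_c = 0$ for single-edge clusters and trees. Exact ties break
toward the finer (higher-similarity) cut — deterministic and favoring
smaller, more interpretable communities. Only clusters spanning at least
three nodes are communities; a strongly connected dyad can therefore be
*unassigned*, which is exactly the phenomenon observed for strongly
paired beverages. Similarity is computed on the unweighted edge set (a
weighted variant would need a convention the method's description never
states). Nested clusters at the chosen cut are reported as distinct
communities. A node's centrality is the number of communities containing
it; nodes in two or more are *central*. `brute_force_communities()`
re-derives the optimum independently (over all cut levels, and over all
set partitions into connected clusters for up to six edges) and backs an
exhaustive small-graph equivalence suite.

## Comparing meal and habitual networks

Edges are compared as unordered node pairs plus the sign of the partial
correlation ("direction-specific"); a sign-agnostic mode exists for
sensitivity. Only edges inside $\ge 3$-node components enter, and
multiple qualifying components of one meal are pooled. Reported
quantities: the percentage of each meal network's edges present in the
habitual network (one decimal), the percentage of habitual edges absent
from every meal network, sign-discordant pairs, and per-network mean and
maximum $|\rho|$. An empty network yields an explicit `"empty"` marker,
never 0%.

One caution discovered while validating the attenuation phenomenon on
synthetic cohorts: comparing *mean $|\rho|$ over each network's own
recovered edges* is selection-confounded. The habitual table has 814
rows against ~2,400 meal occurrences, so its cross-validated model keeps
only the strongest few edges, raising its within-network mean even when
every matched relation is weaker habitually. The faithful check is
paired: for node pairs present in both a meal and the habitual network,
the meal-level $|\rho|$ exceeds the habitual one on average — which the
test suite asserts, while the unpaired summary comparison is retained
(and documented as failing) for transparency.

## Numerical choices

* Skeptic matrices need not be positive semidefinite (tied, zero-heavy
  columns); eigenvalues are clipped at `1e-4` with a unit-diagonal
  rescale, iterated because the rescale itself can push eigenvalues back
  below the floor.
* Glasso convergence: outer sweeps stop when the working covariance
  changes by less than `tol` × mean off-diagonal; the reported KKT
  residual is checked against `1e-5`.
* Edge existence: `|pcor| > 1e-8` (exact lasso support).
* All randomness — graph construction, amounts, fold assignment, plot
  layouts — flows from named seeds; equal seeds give byte-identical
  pipeline outputs, verified by manifest checksums.
* Test problem sizes: estimator consistency at $n = 10{,}000$, $p = 5$;
  copula invariance at $n = 5{,}000$; structure recovery at $p = 20$,
  $n = 2{,}000$ over 10 replicates; cohort-level checks on the full
  814-participant preset over 2–5 replicates; community oracle
  equivalence exhaustively on all connected labeled graphs on up to 5
  vertices (≤ 8 edges) plus seeded random graphs on 6–9 vertices.

## Known limitations

* The original cohort's concrete networks, community counts and overlap
  percentages depend on undeposited data and are not reproduction
  targets; the synthetic preset reproduces the *mechanisms* (skew, zero
  inflation, meal-specific structure, habitual mixing), not the cohort.
* Likelihood-CV selection, even refitted, has no model-selection
  consistency guarantee; stability selection and EBIC are deliberately
  out of scope (hooks exist via the exposed grid and scoring options).
* The generator's single latent graph per meal cannot express
  higher-order dependence (e.g. amount-dependent co-occurrence).
* Kendall's tau-b costs $O(n^2)$ per pair in the current implementation
  path via `stats::cor`; at cohort sizes Spearman is the practical
  default.
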