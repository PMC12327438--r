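---
title: "Approximate cross-validated means for hierarchical models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate cross-validated means for hierarchical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical method implemented by `axecv`, the
modelling assumptions it rests on, the defaults and the reasons for them, and
the numerical and design decisions that are not forced by the mathematics.

## 1. Model and estimator

The package targets Bayesian hierarchical regression models of the form

$$
Y \mid \beta, \phi \sim N(X\beta, \phi^2 I), \qquad
\beta = (\beta_1, \beta_2), \quad
\beta_1 \sim N(0, C), \quad \beta_2 \sim N(0, \Sigma),
$$

with hyperpriors on $\Sigma$ and $\phi$. $\beta_1$ collects fixed effects
(flat prior by default, $C^{-1} = 0$), $\beta_2$ collects random effects.
Supported structures for $\Sigma$ are `iid_by_term` ($\sigma_t^2 I$ per random
term) and a proper conditional autoregressive (CAR) structure
$\Sigma^{-1} = \tau^{-2}(D - \rho W)$ on an adjacency graph $W$ with degree
matrix $D$.

Conditional on the variance parameters, the posterior of $\beta$ is Gaussian
with mean

$$
E(\beta \mid \Sigma, \phi, Y) = \phi^{-2} V X' Y, \qquad
V = \left(\phi^{-2} X'X + \mathrm{blockdiag}(C^{-1}, \Sigma^{-1})\right)^{-1}.
$$

The cross-validation estimator replaces the per-fold posterior by this
conditional mean with the **full-data** posterior means
$\hat\Sigma = E(\Sigma \mid Y)$ and $\hat\phi = E(\phi \mid Y)$ plugged in:
for a fold holding out rows $s$, solve the system above on the training rows
only and predict $X_s \hat\beta_{-s}$ (`axePredictLmm`). Each fold costs one
Cholesky solve of a $P \times P$ system. The justification is that the
posterior means of variance parameters are far more stable under deletion of
one cluster than the coefficient posterior itself; as the number of clusters
$J$ grows, $E(\phi \mid Y_{-s})/E(\phi \mid Y) \to 1$ and the approximation
error vanishes. The test suite verifies this empirically: the per-fold
relative movement of the plug-ins and the gap between the approximation and
per-fold MCMC both decrease in $J \in \{5, 10, 20, 40\}$.

**Fold plans.** `foldPlan(data, "lco")` holds out all rows of one cluster at a
time — the fold structure that importance-sampling CV approximations handle
poorly, because a whole block of correlated data leaves the posterior at once.
`"loo"` is the singleton special case, `"custom"` accepts user folds.
A validity invariant is enforced at construction: the rows of a cluster must
be exactly the rows with nonzero entries in that cluster's random-effect
column, so deleting the fold genuinely removes all information about the
corresponding $\theta_j$.

**Generalized linear mixed models.** For binomial-logit and Poisson-log
families, the model is linearized by the iteratively reweighted least squares
working response

$$
\tilde Y_i = X_i\beta + (r_i - u_i)\, g'(u_i), \qquad
w_i = \frac{a_i}{\phi^2\, v(u_i)\, g'(u_i)^2},
$$

where $r_i$ is the response on the mean scale (proportion for binomial with
$a_i$ trials, rate for Poisson with exposure $a_i$), $u_i = g^{-1}(X_i\beta)$,
and $v$ the variance function. At the full-data IWLS convergence
(`iwlsFit`), $\tilde Y$ and $w$ are **frozen**; each fold is then a weighted
penalized solve on the training rows and predictions are mapped back through
$g^{-1}$ (`axePredictGlmm`). Freezing matters: it keeps the per-fold cost at
one solve and makes held-out responses enter only through the full-data fit —
a contract the tests check by flipping held-out responses after the full fit
and asserting the predictions do not move. Optional `refineIters` re-run IWLS
on the training rows starting from the frozen-weight solution; in the tests
the refinement limit coincides with a from-scratch training-data IWLS fit to
1e-6, and with the default `refineIters = 0` the gaussian-identity family
reduces *exactly* to the linear path.

## 2. Ground truth and diagnostics

**Manual CV oracle.** `gibbsLmm` implements a blocked Gibbs sampler: the full
coefficient vector is drawn exactly from its Gaussian conditional via a
Cholesky factor of the precision; scale parameters use conjugate
inverse-gamma updates, slice sampling for half-$t$ priors, and for CAR a
conjugate $\tau$ update plus slice sampling of $\rho$ with the log-determinant
evaluated through precomputed eigenvalues. `mcmcGlmm` uses per-coordinate
adaptive random-walk Metropolis within Gibbs (target acceptance 0.3,
adaptation frozen after burn-in so the chain is Markov when retained draws
begin). `mcvPredict` re-runs the sampler on every training set — the ground
truth the approximation is judged against — and reports batch-means Monte
Carlo standard errors per prediction, so "agreement" can always be stated in
MC-SE units rather than arbitrary tolerances.

**LRR diagnostics.** For a common fold $s_j$,
$\mathrm{LRR}_j = \log(\mathrm{SSE}^{\text{approx}}_j / \mathrm{SSE}^{\text{MCV}}_j)$
on the mean scale. The percentage curve maps $x \in [0, \log 2]$ to the
fraction of folds with $|\mathrm{LRR}| \le x$; its area, normalized by
$\log 2$, is a single $[0,1]$ quality score (exact step-function area, no
grid). $\log 2$ caps the domain because beyond it the approximation's RMSE is
more than $\sqrt{2}$ times off. A tolerance $\delta = 0.25$ corresponds to the
RMSE-ratio band $e^{\pm 0.25} \approx (0.78, 1.28)$.

**AXE+.** Running MCV on *all* folds defeats the purpose, so `axePlus` runs it
on `kFolds` folds chosen by a policy and decides `run-full-MCV` iff
$|\overline{\mathrm{LRR}}| > \delta$ or $\mathrm{sd}(\mathrm{LRR}) > \delta$.

## 3. Defaults and why

| Parameter | Default | Rationale |
|---|---|---|
| sampler draws `M` / `burn` / `chains` | 2000 / 1000 / 4 | enough retained draws that batch-means MC-SEs of posterior means are small relative to the effects tested; multiple chains feed the combined MC-SE |
| scale hyperpriors | half-$t(3,\ 2.5)$ on standard deviations | weakly informative, heavy-tailed; proper even with few clusters, near-flat where data are informative |
| fixed-effect prior | flat ($C^{-1} = 0$) | standard default; an explicit pre-check rejects folds whose removal empties a flat-prior column (rank deficiency) instead of silently regularizing |
| `refineIters` | 0 | the frozen-weight solution is already the estimator; refinement is a diagnostic, not the default |
| IWLS | tol 1e-8, max 100 iterations, honest `converged` flag | convergence to solver precision on the scale of the working response |
| LRR tolerance `delta` | 0.25 | RMSE-ratio band (0.78, 1.28), tight enough to be practically indistinguishable |
| AXE+ `policy` | `"largest"` | largest folds move the plug-ins most, so they bound the approximation error; `"extreme"` and `"stratified_random"` are offered for cluster-size-skewed designs |
| mean clipping | 1e-8 | keeps IWLS weights finite when fitted means hit the boundary; a warning reports clipping |

## 4. Synthetic-data generators

- `simulateLmm` / `simulateGlmm`: random-intercept designs with optional
  slope covariate, balanced or per-cluster sizes. They emulate the canonical
  grouped-data setting; they do **not** emulate crossed random effects or
  heteroscedastic noise.
- `simulateCar`: a rook-adjacency lattice with
  $\theta \sim N(0, \tau^2 (D - \rho W)^{-1})$, emulating small-area spatial
  studies; correctness is tested by comparing sample covariances of 5000
  draws against the dense inverse.
- `radonSubsetsDesign`: a grid over $J \in \{3,4,6,9,12\}$ clusters and
  held-out fraction $\delta \in \{0.3, \dots, 0.7\}$ with $N = 100$ rows; the
  test cluster holds $\lceil \delta N \rceil$ rows and a single fold is
  evaluated. This emulates the stress regime where a large fraction of the
  data leaves with one cluster — the regime where the plug-in assumption is
  weakest — and the acceptance tests confirm mean $|\mathrm{LRR}|$ falls with
  $J$ and shows no monotone trend in $\delta$.

Problem sizes used in the test suite ($J$ up to 40, $N$ up to a few hundred,
short chains of 400–1500 retained draws) were chosen so that the entire suite
runs in minutes on one CPU while keeping every Monte Carlo assertion inside
3 MC-SE bands; they are the package's own choices, not externally mandated.

## 5. Numerical choices

- **Cholesky with jitter fallback.** All solves go through a Cholesky of the
  precision; on failure, jitter `1e-10 * mean(diag)` is added and escalated
  by a factor 100 at most 3 times before erroring. Structural rank deficiency
  (a flat-prior column emptied by a fold) is caught by an explicit pre-check
  so it errors with the fold and column names rather than being masked by
  jitter.
- **Exact AUC.** The area under the percentage curve is computed as the exact
  mean of $\max(\log 2 - \min(|\mathrm{LRR}|, \log 2), 0)$, so the endpoint
  identities (all-zero LRRs give normalized area exactly 1; all beyond
  $\log 2$ give raw area exactly 0) hold in floating point, and grid-based
  areas converge to it under refinement.
- **Zero-SSE folds.** A fold where manual CV is exact gives an undefined
  ratio; it is reported non-finite, excluded from the summary, and counted in
  the report rather than silently dropped.
- **Seeding.** All stochastic entry points take integer seeds; nested
  streams (chains, folds) are derived by a fixed integer mixing function so
  that runs are bit-identical given the seed and no two streams collide.

## 6. Design decisions on points the mathematics leaves open

- **Plug-in rebuilt from parameter means.** $\hat\Sigma$ is reconstructed
  from the posterior means of the *scale parameters* ($\sigma_t$, or
  $(\tau, \rho)$ for CAR), not from the mean of the matrix $\Sigma$ itself.
  This keeps the plug-in inside the parametric family (guaranteed positive
  definite, CAR structure preserved) and matches how the estimator is used.
- **Mean-scale convention for GLMMs.** Responses, predictions, and LRR
  errors for binomial/Poisson are on the proportion/rate scale with trials or
  exposure entering the weights. Chosen so that the gaussian-identity family
  reduces *exactly* (not just asymptotically) to the linear-model path — a
  reduction the tests assert at 1e-12.
- **Unstructured $\Sigma$.** The solver path accepts a fixed unstructured
  positive-definite $\Sigma^{-1}$ plug-in, but the internal samplers do not
  place a prior on an unstructured covariance (that would need an
  inverse-Wishart block of limited value for the cluster designs targeted
  here); `gibbsLmm` rejects such configurations explicitly rather than
  sampling from a model it does not implement.
- **AXE+ selection policies.** Which folds to audit is a heuristic question.
  `"largest"` is the default on the error-bounding argument above;
  `"extreme"` (largest + smallest) probes both ends of the plug-in stability
  spectrum; `"stratified_random"` gives an unbiased audit when cluster sizes
  are uniform.
- **Parameter-recovery reading.** With $J = 40$ clusters the noise variance
  $\phi$ is informed by all $N = 400$ rows but the cluster scale $\sigma$ only
  by 40 latent draws, so recovery assertions hold *all* seeds to 15% for
  $\phi$ and the *median* seed to 15% (all within 40%) for $\sigma$ —
  reflecting the sampling distribution of the estimand, not sampler error.
  Where population truth is too loose a yardstick, the sampler is instead
  compared against REML estimates on the same realized data.
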