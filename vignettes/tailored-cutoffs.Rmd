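---
title: "Tailored cutoffs for fit indices: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tailored cutoffs for fit indices: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gofcutoffs)
```

This vignette documents the statistical content of `gofcutoffs`: the
population and analysis models, the estimators and their test statistics,
the tailored-cutoff machinery, and the numerical and design decisions that
were genuinely open when the package was written. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Population models and the simulation design

Each scenario of the crossed design pairs a *population* model with an
*analysis* model:

* **dim_correct** — one factor; one-factor analysis model (correct).
* **dim_misspec** — two factors correlated at .70/.50/.30, analysed as
  one factor. The misspecification grows as the true correlation falls:
  collapsing two nearly identical factors (r = .70) is a mild error,
  collapsing two clearly distinct ones (r = .30) a severe one.
* **cross_correct** — two factors (r = .00 or .30), no cross-loadings;
  two-factor analysis model with the correlation estimated when the
  design correlation is .30 and fixed to zero when it is .00.
* **cross_misspec** — as cross_correct, but a proportion .17/.33 of the
  indicators carry a population cross-loading of .20/.30 that the
  analysis model omits.

All factors have unit variance; every indicator's continuous response has
unit variance, so the residual variance is
`1 − (λ₁² + λ₂² + 2 λ₁ λ₂ r)`. Configurations implying a non-positive
residual variance are rejected. Proportions map to counts by rounding
(`.17 × 6 → 1`, `.33 × 6 → 2`, `.17 × 12 → 2`, `.33 × 12 → 4`), and the
cross-loadings sit on the *first* indicators of factor 2, loading on
factor 1 — a fixed, documented placement so that scenario ids are
reproducible. Analysis models never estimate cross-loadings; misfit only
ever arises from omission. Each family crosses estimator (ML, MLR, DWLS,
WLSMV), 6/12 indicators, 3/5/7 response options, symmetric/asymmetric
response distributions, loadings .40/.60/.80, and N = 200/500/2000 —
6048 cells in total, enumerated in a fixed lexicographic order so a
configuration always produces the same scenario sequence and ids.

## Ordinal data generation

Continuous responses are drawn as correlated standard-normal factors plus
independent normal residuals and cut at `K − 1` thresholds on the
standard-normal scale. The thresholds are not free constants: they are
solved so the implied categorical distribution of the scores `1..K`
matches target moments — skewness 0 (symmetric cells) or 0.65
(asymmetric), excess kurtosis ≈ −0.80 in both. The solver parameterizes
the category probabilities directly (softmax over free logits, a
symmetric construction for symmetric targets so the skewness is exactly
zero and the thresholds exactly symmetric) and minimizes the squared
deviation from the targets, then sets τ = Φ⁻¹(cumulative probabilities).
Multiple deterministic starts guard against local minima; the result is
accepted only if the skewness lands within 1e−3 and the kurtosis within
0.05 of target. With K = 3 and both targets active the two free
probabilities are exactly determined; for K = 5, 7 the targets are hit to
optimizer precision. Because the solver is a documented construction
rather than a published table, quantities that depend on the exact
categorization carry extra tolerance in the acceptance checks.

A dataset is accepted only if every category of every column has at least
five observations — the categorical estimators need all thresholds
estimable — otherwise the *whole* dataset is regenerated from the next
point of the seeded stream (the rule reads most naturally at dataset
level; single-column patching would distort the joint distribution). The
resample count is recorded; a cap (default 1000 attempts) turns
pathological sparsity into an explicit error rather than a livelock. The
sparse corner of the design (N = 200, seven asymmetric options, where the
rarest category has probability ≈ .058 and expected count ≈ 11) is where
regeneration concentrates, consistent with the design's intent.

Seeding is counter-based: each replication derives a 31-bit seed from
`(master_seed, scenario_id, replication)` via a Lehmer-style string hash,
so results are independent of execution order and stable under
resharding.

## Estimators

**ML** treats the codes `1..K` as numeric, uses the divisor-N sample
covariance, and minimizes
`F_ML = log|Σ(θ)| + tr(S Σ⁻¹) − log|S| − p` by quasi-Newton with an
analytic gradient; `T = N·F` at the optimum. The N-vs-(N−1) multiplier is
a documented constant; at N = 200 it shifts T by under 0.5%, far below
any tolerance used here. Identification fixes the first loading per
factor to 1; factor variances, the factor covariance (when estimated) and
residual variances are free, with variances optimized on the log scale.
Free loadings start at 1 (their population ratio under this
identification), the factor variance at the mean within-factor
covariance — these starts are a robustness choice, and only optimizer
*failures* are culled: converged solutions with negative residual
variances (Heywood cases) are retained and flagged, since the culling
rule of the study conditions names non-convergence only.

**MLR** rescales the ML statistic by `c = tr(U Γ)/df`, with Γ the
fourth-moment (divisor-N, consistent with `T = N·F`) asymptotic
covariance of the sample covariances and
`U = W − WΔ(Δ′WΔ)⁻¹Δ′W` the normal-theory residual weight matrix at the
ML solution. Parameter estimates and SRMR are untouched.

**DWLS** estimates thresholds from the univariate margins and each
polychoric correlation by maximizing the bivariate-normal likelihood of
the pair's contingency table with thresholds fixed (the classical
two-step). The bivariate-normal rectangle probabilities use a hybrid
Gauss–Legendre quadrature accurate to ~1e−14 over the full correlation
range. The asymptotic covariance Γ of the correlations propagates the
threshold estimation step through the stacked estimating equations
(sandwich form); its diagonal supplies the DWLS weights and the full
matrix feeds the WLSMV adjustment. The model is fitted to the correlation
structure only (thresholds are saturated), under the standard theta
convention — residual variances of the latent responses fixed at 1, first
loading per factor at 1 — with the implied matrix standardized to a
correlation matrix. With saturated thresholds this parameterization
choice cannot affect fit or the standardized solution, which is why the
package states it once and offers no delta switch.

**WLSMV** shares the DWLS estimates and applies the df-preserving
scaled-and-shifted correction: with `M = UΓ`,
`a = sqrt(df / tr(M²))`, `b = df − a·tr(M)`, `T* = a·T + b`, recorded as
`scaling_factor = 1/a` and `shift = b` so the transformation is exactly
reconstructable. The Satterthwaite-df variant is deliberately not the
default, matching the common default of the era's SEM software.

The independence baseline (free variances / saturated thresholds, zero
covariances or correlations, `df = p(p−1)/2`) uses the same statistic
variant as the target model; CFI and RMSEA for MLR/WLSMV are computed
from the *adjusted* statistics of both models (the "scaled" index
convention — which variant the reference tables used is not documented,
and this is the standard software output of the period).

## Indices and tailored cutoffs

CFI, RMSEA and SRMR follow their standard guarded definitions
(`compute_cfi`, `compute_rmsea`, `compute_srmr`); SRMR averages squared
standardized residuals over the lower triangle including the diagonal,
which contributes zeros for correlation-structure fits.

Tailored cutoffs are empirical quantiles over converged replications of a
correctly specified scenario: the 95% quantile for χ², χ²/df, RMSEA,
SRMR, the 5% quantile for CFI, at α = .05 by default. The quantile
estimator interpolates between order statistics (type 7, the default of
most statistical environments); the reference analysis does not state its
quantile type, and at 1000 replications the tail quantile types differ by
less than the stochastic tolerance of any check here. `rejection_rates`
scores correct-specification records against their own cutoffs (Type I)
and misspecified records against the cutoffs of their correctly specified
twin — the cell agreeing on all non-misspecification features (Type II).

The equation-based predictor evaluates, per index, a 74-term linear form:
estimator dummies against the ML reference, main effects, quadratics for
characteristics with more than two levels, all two-way interactions, the
sample size divided by 1000, all features raw and uncentered, and the
correlated-factors indicator entering only through its interaction with
the number of factors. SRMR has no MLR/WLSMV terms because it is
identical within the ML/MLR and DWLS/WLSMV pairs; the predictor maps
those estimators to their SRMR-equivalent twins. χ² predictions carry a
permanent warning — they are tied to the df of the simulated models.
`fit_cutoff_regression` refits the same term structure to any cutoff
table by OLS (unweighted; no weighting scheme is documented for the
reference fit) and errors on rank deficiency, naming the aliased terms.

## What the generator emulates — and what it does not

The generator reproduces the study conditions: normal latent factors,
unit-variance indicators, moment-matched categorization, the five-count
acceptance rule. It does not emulate missing data, non-normal factors,
unequal loadings within a factor, more than two factors, or real-world
threshold heterogeneity across items. Passing tests therefore demonstrate
calibration *under these conditions*; they do not certify the cutoffs for
data violating them — which is precisely the package's own argument for
scenario-specific simulation when in doubt.

## Problem sizes used by the tests and the acceptance script

The worked-example checks use the study's own 1000 replications
(one-factor, six indicators, N = 200; ML with seven asymmetric options at
loadings .40/.80, WLSMV with five symmetric options at loading .60). The
factor-correlation-inflation checks pool a stratified subset of the
correlated two-factor cells: estimators ML and DWLS — which carry the
parameter estimates of the ML/MLR and DWLS/WLSMV pairs *exactly*, so the
pooled median over the two is the pooled median over all four — both
indicator counts, all three loadings, N ∈ {200, 500}, five symmetric
options, both misspecification magnitudes where applicable, with eight
replications per cell. Options and distribution shape are held fixed
there because the estimated factor correlation is insensitive to them
relative to its sampling noise at these sizes; loadings, magnitudes and
proportions — the drivers of the inflation — are covered in full.
Unit tests run on single datasets or tens of replications.

## Known limitations

* The built-in grid supports at most two factors; the predictor refuses
  factor counts outside {1, 2}.
* Polychoric estimation flags, but does not remediate, correlations at
  the search boundary (|ρ̂| > .999 − 1e−4).
* The full 6048-cell, 1000-replication grid is supported by the engine
  but takes CPU-days in one process; `run_grid` is deterministic under
  sharding precisely so that users can split it.
* Standard errors of parameter estimates are not reported; the robust
  corrections are computed for the test statistics only.
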