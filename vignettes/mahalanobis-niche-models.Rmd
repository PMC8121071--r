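---
title: "Mahalanobis distance niche models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mahalanobis distance niche models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A presence-only niche model needs nothing but an m×n matrix of occurrence
records in environment space. Its location μ̂ (an n-vector) and scatter Σ̂
(an n×n matrix) define the squared Mahalanobis distance

$$D^2(\mathbf{x}) = (\mathbf{x}-\hat\mu)^\mathsf{T}\hat\Sigma^{-1}(\mathbf{x}-\hat\mu)$$

of any environment **x** from the model's centre. If the occurrences were
drawn from a multivariate normal, D² follows a chi-squared distribution
with n degrees of freedom, so `nicheProbability()` converts it to
P(χ²ₙ ≤ D²) (the outlier reading) or its complement P(χ²ₙ > D²) (the
niche reading: the probability that **x** is within an elliptical
fundamental niche). The key assumption is therefore *elliptical
(multivariate normal) niche shape*; the model says nothing about skewed or
bimodal responses, and it models the fundamental niche, not the realised
one.

Three estimators of (μ̂, Σ̂) are provided:

* `estimateSample()` — column means and the m−1-denominator covariance.
* `estimateMCD()` — minimum covariance determinant: the h-subset with the
  smallest covariance determinant. Fast mode draws `n_trials` random
  elemental (n+1)-point starts and refines each with concentration
  steps — compute all D² under the current estimate, keep the h smallest,
  re-estimate — which provably never increase the determinant; iteration
  stops when the determinant stops decreasing (relative tolerance 1e−12)
  or after `max_csteps`. Exhaustive mode enumerates all C(m, h) subsets
  (refused above 10⁶) and serves as a small-sample oracle.
* `estimateMVE()` — minimum volume ellipsoid: for each elemental subset
  with mean c and covariance C, the ellipsoid covering exactly h points
  has squared radius λ (the h-th smallest distance) and volume ∝
  √(det(C)·λⁿ); the candidate minimising det(C)·λⁿ wins.

Subset covariances use the h−1 denominator throughout (the sample
convention; some of the robust-estimation literature divides by h).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | `NULL` → h = ⌊(m+n+1)/2⌋ | retained fraction, h = ⌊k·m⌋; k ≈ 0.55 is maximally robust, k → 1 classical |
| `n_trials` | 500 | random elemental starts; ample for n = 2 (convergence is usually reached from many basins) |
| `max_csteps` | 100 | safety cap; convergence takes ≪ 10 steps in practice |
| `reweight` | `TRUE` | one-step reweighting (below) |
| `rescale` | `TRUE` | chi-squared consistency rescaling of the *raw* estimates when `reweight = FALSE` |
| `seed` | `NULL` | makes the subset search reproducible |

MCD enforces m ≥ 5n (its standard feasibility rule; with n = 2, m ≥ 10);
MVE only needs h ≥ n + 1. Ties in "the h smallest distances" break to the
lowest row index; ties in the objective keep the first candidate found —
both so a seeded fit is bit-reproducible.

### Reweighting and rescaling

Raw h-subset estimates are robust but statistically inefficient, and their
scatter is on the wrong scale for the chi-squared probability transform.
Two remedies are implemented:

* **One-step reweighting** (default): the subset covariance is inflated by
  the small-sample factor (1 + 15/(m−n))², distances are cut at an
  empirically consistency-corrected 97.5% chi-squared fence,
  `qchisq(0.975, n) · quantile(D², h/m) / qchisq(h/m, n)`, and the
  classical mean/covariance of the points inside the fence is returned.
  This is the finishing step used by the classical robust-covariance
  implementations in mainstream statistical software, and without it the
  idealised-sample correlations of the robust methods drop well below
  those the experiments are meant to exhibit. It is skipped at h = m,
  where the estimator is classical by construction, so the k → 1
  equivalence with `estimateSample()` is exact.
* **Consistency rescaling** (`reweight = FALSE, rescale = TRUE`): MCD
  scatter × median(D² over retained)/qchisq(0.5, n); MVE scatter λC /
  qchisq(h/m, n). This keeps the raw subset estimates but calibrates their
  scale; the MVE version is undefined at h = m (the quantile is infinite)
  and errors there. Because the exact internal correction used by any
  particular software stack is not recoverable from its description, both
  toggles are exposed rather than hard-wired.

`objective` on the returned fit always records the raw criterion (the
determinant for MCD, det(C)·λⁿ for MVE), so fast-versus-exhaustive
comparisons are unaffected by either remedy.

## The virtual-ecology machinery

The truth is a virtual species with growth rate
λ_F(x) = λ_max·exp(−½(x−μ)ᵀΣ⁻¹(x−μ)) — an elliptical niche with optimum
μ = (7.5 °C, 1800 mm), λ_max = 2.5 and a strong negative
temperature–rainfall covariance (Σ = [[2, −950], [−950, 800000]]).
Quadratic forms are evaluated through a Cholesky solve rather than an
explicit inverse; the two agree to 1e−10 on the defaults (tested), and the
solve is the numerically stable choice. Detection follows the logistic
P_d = 1/(1+e^(−10(λ_F−0.5))): near 0 where the population cannot persist,
near 1 above λ_F ≈ 1.

* `sampleIdealised()` rejection-samples N(μ, Σ) through P_d. A
  consequence worth knowing: the accepted sample is *not* N(μ, Σ) — it is
  symmetric about μ but shrunken (its covariance is roughly half Σ), which
  is why fitted scatters are tighter than Σ even with perfect data.
* `generateSpace()` builds the finite sampling space standing in for a
  region's climate grid: N points (default 2000, uniform weights 1/N —
  one per pseudo-raster cell, sampled by cell) from a truncated
  two-component bivariate-normal mixture. The default mixture was chosen
  once so that the space has the structure the error/bias experiments
  need — 80% of mass in cool/dry environments far from the niche optimum,
  20% overlapping the niche edge from below, hard bounds at (−2, 16) °C ×
  (50, 6000) mm — giving under 30% of cells with P_d > 0.5 (so uniform
  draws mostly represent the climate space, not the niche) and placing
  the detectable mass on one side of the niche (so detection-weighted
  draws are genuinely biased, not merely filtered).
* `contaminate()` uses replacement semantics: errors
  (`drawUniform()`) and bias (`drawBiased()`, rejection through P_d)
  displace idealised rows at uniformly chosen positions, keeping m fixed —
  the experiments vary contamination at constant sample size, so
  augmentation would confound the two. Counts are round-half-up, exact on
  the canonical m = 100 grids. Replaced positions are chosen at random;
  since idealised rows are i.i.d., this is distributionally equivalent to
  regenerating the sample.
* Rejection loops carry a 10⁶-attempt cap and raise classed errors
  (`biasInfeasibleError`, `samplingInfeasibleError`) rather than hang when
  a space offers essentially no detectable environments.

What the generator does *not* emulate: spatial autocorrelation, the
geography linking climate cells (there are no coordinates, only
environments), unequal cell frequencies (weights are supported but default
uniform), and climate-space shapes more complex than a two-component
mixture. Passing tests therefore show the estimators behave as expected
under a *stylised* climate space with a known elliptical truth — not that
any particular real data set is error- or bias-dominated.

## The experiments

`runExperiment()` reproduces the three designs: sample size (m from 10 to
160 in steps of 15, idealised), error (m fixed at 100, error fraction 0 to
50% in steps of 5%) and bias (m = 100, bias 0 to 100% in steps of 10%),
each condition replicated (default 500) and fitted with the sample
estimator plus MCD and MVE at each k ∈ {0.55, 0.75, 0.95}. All methods
score the *same* sample per replicate (a paired design, which is what
"each sample ... was applied to each method" implies and what minimises
between-method Monte-Carlo variance). Performance is the correlation
between the known λ_F and the fitted P(χ²₂ > D²) over the sample rows;
Pearson by default — both quantities are monotone transforms of quadratic
forms, so Pearson and Spearman agree closely, and a flag exposes Spearman
for sensitivity analysis. Summaries are medians and quartiles
(linear-interpolation type-7 quantiles, stated so they are
bit-reproducible). Degenerate fits and undefined correlations are logged
as failed replicates and excluded from quantiles, with counts in the
summary.

Reproducibility uses a splittable child-seed scheme: replicate r of
condition c under mode id d hashes (seed, d, c, r, cell) through a 69069
multiplicative-congruential fold modulo 2³¹−1 (exact in doubles), so any
single replicate can be regenerated in isolation — this is tested.

The test suite runs the experiments at desk scale — 50 replicates at the
diagnostic conditions (m ∈ {10, 55}; e = 30%; b = 60% with k ∈ {0.55,
0.95}) — which is ample for the median orderings it asserts: the
classical estimator wins at very small m, the robust estimators win under
errors, and under heavy bias the classical estimator wins at k = 0.55
while the gap vanishes by k = 0.95.

## Known limitations

* Elliptical-niche assumption throughout; no skewed or multimodal niches.
* n is general in the code, but all defaults and experiments are the
  two-dimensional temperature × rainfall setting; very high dimensions
  would need partitioned subset search, which is out of scope.
* No geographic projection: everything lives in environment space, and
  "errors" are environment-space draws, not georeferencing models.
* The MVE search is the classical elemental resampling approximation; the
  exhaustive mode bounds its optimality only on small instances.
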