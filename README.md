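# nicheD2

Presence-only ecological niche models built on the Mahalanobis distance,
with robust multivariate location and scatter estimators, and a
virtual-ecology toolkit for studying how sample size, errors and sampling
bias affect them.

## The problem

Niche models are routinely fitted to natural history observations —
occurrence records with environmental covariates attached — that contain
both *errors* (misidentified or misgeoreferenced records that land anywhere
in a region's climate space) and *bias* (over-representation of commonly
occurring or accessible environments). The Mahalanobis distance

D²(x) = (x − μ̂)ᵀ Σ̂⁻¹ (x − μ̂)

measures how far an environment x lies from the centre of the fitted
multivariate normal, and P(χ²ₙ > D²) turns it into the probability that x
lies within an elliptical fundamental niche. Everything hinges on how the
location μ̂ and scatter Σ̂ are estimated:

* **sample** — column means and the sample variance-covariance matrix;
  efficient, but dragged by outliers;
* **MCD** — the minimum covariance determinant: the mean/covariance of the
  h-point subset with the smallest covariance determinant, found by random
  elemental starts refined with concentration steps (C-steps);
* **MVE** — the minimum volume ellipsoid: the smallest ellipsoid covering
  h points, approximated by elemental-subset resampling.

The retained fraction k = h/m (0.5 < k ≤ 1) controls the robust methods:
k ≈ 0.55 is maximally robust to errors but latches onto concentrated bias;
k → 1 recovers the classical estimator. Both robust estimators finish with
the standard chi-squared-fenced one-step reweighting, which restores most
of the classical estimator's efficiency while keeping outlier resistance.

The package also ships the machinery to study this with a known truth: a
virtual species with an elliptical Gaussian niche (growth rate
λ_F(x) = λ_max·exp(−½(x−μ)ᵀΣ⁻¹(x−μ)), defaults λ_max = 2.5,
μ = (7.5 °C, 1800 mm), Σ = [[2, −950], [−950, 800000]]), a logistic
detection filter P_d = 1/(1+e^(−10(λ_F−0.5))), a synthetic finite climate
space, error/bias contamination of samples, and replicated experiments
scored by the correlation between the known λ_F and the modelled
P(χ²₂ > D²).

## Worked example

```r
library(nicheD2)

np  <- nicheParams()                      # the default virtual species
occ <- sampleIdealised(np, 100, seed = 42)
occ
#> Occurrence sample: m = 100 points
#>   provenance: idealised=100, error=0, bias=0

fit <- estimateMCD(occ, estimatorConfig(k = 0.55, seed = 42))
fit
#> Multivariate location and scatter (mcd)
#>   location:    7.670395, 1707.944729
#>   h: 55
#>   objective: 35279.59
#>   scatter:
#>              [,1]        [,2]
#> [1,]    0.8215774   -410.2091
#> [2,] -410.2090741 429564.8858

round(performanceCorrelation(np, occ, estimateSample(occ)), 3)
#> [1] 0.983
round(performanceCorrelation(np, occ, fit), 3)
#> [1] 0.952
round(predictNiche(fit, rbind(c(7.5, 1800), c(10, 900)))$p_niche, 3)
#> [1] 0.982 0.028
```

The fitted location sits near the niche optimum (7.5, 1800); the MCD
scatter is tighter than the true Σ because the idealised sample is
detection-filtered and only the central 55% of it is retained before
reweighting. Both models rank the niche optimum as near-certainly inside
the niche (p = 0.982) and a hot dry environment as outside (p = 0.028),
and both correlate strongly with the true growth rate over the sample.

The experiment pipeline compares all estimators across conditions:

```r
ex <- runExperiment(experimentConfig("error", e_values = 0.30,
                                     k_values = 0.55, reps = 50, seed = 12))
ex$summary[, c("method", "k", "median_r", "q1_r", "q3_r")]
#>   method    k  median_r  q1_r  q3_r
#>      mcd 0.55     0.954 0.918 0.967
#>      mve 0.55     0.953 0.926 0.969
#>   sample   NA     0.649 0.571 0.673
```

With 30% errors the robust estimators hold their performance while the
classical estimator collapses; under heavy bias the ordering reverses (see
the methods vignette in `vignettes/`).

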