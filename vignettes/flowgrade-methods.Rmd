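---
title: "Methods: end-product hemodynamic assessment of anastomoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: end-product hemodynamic assessment of anastomoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`flowgrade` scores surgical end-to-side anastomoses from the hemodynamics of
the finished suture rather than from observation of the trainee. This
vignette is the package's own account of the models it implements, the
assumptions they rest on, the synthetic world the tests run in, and the
numerical choices that a maintainer would otherwise have to reverse-engineer
from the code.

## 1. From flow fields to 19 features

The inputs are a triangulated vessel surface carrying a time-resolved wall
shear stress (WSS) vector series over one flow cycle, and a volume series of
velocity and pressure samples with port (inlet/outlet) definitions.
Geometric units are millimetres and stresses Pascal throughout, so spatial
gradients are Pa/mm and vorticity 1/s; velocities are converted to m/s, and
energy loss to W, only when the final feature vector is assembled.

Per surface point `j` with normal `n_j`:

* `TAWSS_j = (1/T) ∫ ‖τ_j(t)‖ dt`
* `OSI_j = ½ (1 − ‖∫ τ_j dt‖ / ∫ ‖τ_j‖ dt)`, clipped to `[0, 0.5]`; points
  with zero integrated magnitude get 0 by convention.
* `RRT_j = [(1 − 2 OSI_j) TAWSS_j]⁻¹`. A fully oscillatory point makes the
  denominator vanish; the value becomes `Inf`, is excluded from the median
  reduction, and the count is attached as an attribute rather than allowed
  to destroy the sample feature.
* `transWSS_j = (1/T) ∫ |τ_j(t) · (n_j × p_j)| dt`, where `p_j` is the unit
  vector of the time-averaged WSS. When the mean vector is degenerate
  (below 1e−12, e.g. a perfectly symmetric full rotation) the perpendicular
  direction is undefined; the point contributes 0 and is counted.
* `WSSG_j`: the per-triangle P1 (linear shape function) surface gradient of
  the TAWSS scalar, averaged onto points with incident-triangle area
  weights. Computing the gradient of the *time-averaged* scalar — rather
  than time-averaging instantaneous component gradients — is a deliberate
  choice: it is well-defined from the same series, exact for linear fields,
  and frame-independent.

All temporal integrals use the trapezoid rule on the (possibly non-uniform)
time grid: second order, standard, and exactly what the closed-form test
fields assume.

Volume quantities (vorticity, helicity density `v·ω`, scalar strain rate
`√(2 S:S)`) come from a least-squares velocity gradient per sample point.
The local model is *quadratic-diagonal* — terms `x, y, z, x², y², z²` on the
neighbor offsets — rather than purely linear: a linear fit is badly biased
at one-sided (wall-adjacent) stencils, where the parabolic profile's
curvature leaks into the slope estimate; with the quadratic-diagonal basis
the gradient is exact for linear fields and for isotropic-curvature
profiles such as Poiseuille flow, and second-order accurate otherwise.
Points without at least six usable neighbors, or with an ill-conditioned
normal matrix (reciprocal condition below 1e−12), are excluded with a
warning.

Port integrals are discrete area-weighted sums (flow rate `Q = Σ w v·d`,
area-averaged pressure and speed); energy loss is the time-median of the
total-pressure flux difference `Σ Q(p̄ + ½ρv̄²)` between inlets and outlet,
and efficiency its complement relative to the inlet flux.

Reduction to the feature vector follows one convention: features not
suffixed `_max` are medians — time first per point (where a temporal
dimension exists), then the spatial median — while `_max` features are the
global maximum over all points and times. Non-finite values are excluded
from medians with a logged count; a feature whose every constituent is
non-finite raises an error naming it. The Reynolds number uses the
standardized 3 mm inner diameter as its characteristic length, because
every geometry is isotropically rescaled to that diameter before feature
extraction (`scale_to_reference_diameter()`), removing size as a confounder
at the cost of anatomical literalism.

A note on scope: the package deliberately contains no flow solver. The
analytic generators (steady and quasi-steady pulsatile Poiseuille, and a
rotating-direction wall shear field) exist because they admit closed-form
values for the indicators — `OSI = ½(1 − sin α/α)` and
`transWSS = τ₀(1 − cos α)/α` for a uniform sweep over `[−α, α]`, the
Hagen–Poiseuille `4μQ/(πR³)` wall shear and `8μLQ/(πR⁴)` pressure drop —
so every indicator implementation is tested against an independent closed
form, not against itself. The pulsatile generator is quasi-steady (no
Womersley profile) for exactly this reason: oracle value over physiological
fidelity.

## 2. The synthetic cohort

Real cohorts of scanned anastomoses are proprietary, so the package ships a
generative model whose structure mirrors what such a cohort looks like
statistically; it emulates a 419-sample, 3-rater study on a continuous
1–10 scale.

* **Features.** A Gaussian copula with a one-factor correlation structure
  (`R = λλᵀ + diag(1 − λ²)`, loadings between 0.3 and 0.75 on a common
  "hemodynamic severity" factor, negative for efficiency-like features)
  with lognormal marginals: positive, right-skewed, correlated — the shape
  of physical hemodynamic quantities. The three dominant adverse indicators
  (transverse WSS, WSS gradient, graft-inlet pressure drop) get log-scale
  spreads of 0.8–0.9: an order of magnitude and more between clean and
  badly distorted anastomoses. That spread is what makes the latent quality
  *materially nonlinear in the raw features*; with narrow marginals the
  log-logistic map below is indistinguishable from linear and tree
  ensembles would have nothing to gain over ridge regression.
* **Latent quality.** An affine combination of log-features passed through
  a logistic link onto the score range. The raw signed weights put the
  largest negative values on `WSS_trans`, `WSSG` and `dp_in2-out` (and a
  substantial one on `Vorticity_max`), encoding the monotone inverse
  relationship between adverse hemodynamics and scored quality. The
  weights are rescaled through the copula correlation so the linear
  predictor is exactly `N(0.79, 0.703²)`; those two constants come from
  normal order statistics — at n = 419 the expected extremes `μ ± 2.9σ`
  map through the logistic link to scores of about 3 and 9.5, the low/high
  ends a rating panel actually uses on a 1–10 scale.
* **Raters.** `r_ij = clip(s_i + b_j + ε_ij)` with per-rater bias
  `b_j ~ N(0, 0.3²)` and noise `ε_ij ~ N(0, σ²)`, clipped at the scale
  bounds because raters cannot leave the scale. The noise SD is derived in
  closed form from the target reliability: under the two-way consistency
  model `ICC3k = σ_s²/(σ_s² + σ_e²/k)`, so
  `σ_e = σ_s √(k(1/ICC − 1))` with `σ_s` computed by numerical integration
  of the score distribution. The default target is 0.846; the realized
  value on generated cohorts lands within a few hundredths of it.

What a green test on this cohort establishes: that the pipeline recovers a
known monotone, nonlinear generative structure from realistically noisy
ratings at realistic sample size. What it does not establish: anything
about scanned-geometry realism, about CFD solver accuracy, or about the
transferability of the fitted models to a real training cohort — the
synthetic features are copula draws, not solutions of flow equations.

## 3. Consensus and reliability

The outcome variable is the sample-wise arithmetic mean of non-missing
ratings (at least two per sample, enforced). ICC(3,k) — two-way mixed,
consistency, average of k raters — is computed from the ANOVA decomposition
of the complete-case sample × rater matrix, `(MS_samples − MS_error) /
MS_samples`, with the standard F-based 95% interval. Consensus uses every
available rating while the ICC uses complete cases only, because the
two-way ANOVA needs a full matrix while the outcome does not. The 0.8
reliability benchmark is exposed as a pass/fail flag; the assessment
pipeline warns but continues below it, since a low-reliability cohort is
still analyzable — its results just mean less.

## 4. The model pool

Six families behind one fit/predict contract: ridge, partial least squares,
kernel support vector regression, random forest, extremely randomized
trees, gradient boosting. The target environment has no regression-ML
packages, so the engines are implemented here: closed-form ridge
(`(XᵀX + αI)⁻¹Xᵀy` on standardized features), NIPALS PLS, SVR by L-BFGS on
a squared (smoothed) ε-insensitive kernel objective, and a compiled CART
engine with presorted feature orders shared by the three ensembles
(bootstrap + best splits for the forest, no bootstrap + uniform random
thresholds for extremely randomized trees, residual boosting with
learning-rate shrinkage, row/column subsampling and an L2 leaf penalty for
gradient boosting). Ridge, PLS and SVR are fit on z-scored features with
the scaler learned on training data only and bundled into the model; tree
ensembles are scale-invariant and fit raw. Predictions align columns by
name, so column order never matters and missing columns fail loudly.

One practical caveat documented rather than hidden: the SVR objective has
flat regions (the ε-tube), so its optimizer is deterministic for identical
inputs but not stable to last-bit input perturbations; tests of the
scaling-bundle contract therefore use the closed-form families.

The default search spaces are conventional wide boxes — ridge penalty
log-uniform on `[1e−3, 1e3]`; PLS components 1–19; SVR kernel
{linear, polynomial, rbf} with log-scaled `C`, `ε`, `γ` and degree
{2, 3, 4}; tree counts 50–500 with depth, leaf-size and feature-fraction
ranges; boosting additionally with log-scaled learning rate, subsampling
fractions and leaf penalty. The tuning behaviour, not the exact box, is
the scientific surface; the boxes are declared in `default_space()` and
overridable per run.

## 5. Evolutionary hyperparameter search

A μ+λ evolution strategy with μ = λ = 30: after the first generation the
working pool holds 60 individuals, and truncation (elitist) selection keeps
the best 30 of the union — the literal reading of "μ = λ individuals are
selected to be parents", and the reason best-so-far fitness is provably
non-increasing. Crossover is uniform per-gene exchange applied with
probability `p_cx`; mutation perturbs each gene with probability `p_mut`
(Gaussian steps of 10% of the domain width, in log space for log-scaled
domains, clipped to bounds; rounded steps for integers; uniform resample
for categoricals). The probabilities follow saturating exponentials,
`p_cx(g) = p_end − (p_end − p_start) e^{−g/τ}` rising from 0.2 to 0.8 and
mutation mirrored falling from 0.8 to 0.2 with τ = 10 generations — an
explicit functional form chosen to realize "exponentially increasing
crossover, decaying mutation" since only the qualitative shape is
specified anywhere. Runs stop at 30 generations or after 10 successive
generations without improvement beyond 1e−9 (an absolute tolerance that
makes float noise not count as progress). Non-finite fitness values are
demoted to worst-possible rather than crashing the search, and counted.

## 6. Nested cross-validation and reporting

Generalization is estimated by 10 outer folds, stratified by
consensus-score quantile bins (4 bins) so the continuous target is balanced
across folds. Within each outer-training portion, a 5-fold inner loop
supplies the fitness (mean MSE) for the ES search; the tuned winner is
refit on the whole outer-training portion and evaluated once on the
held-out fold. Five inner folds is a package choice — it keeps the fitness
evaluation affordable inside the ES budget. Hyperparameter selection never
touches outer-test data; the test suite includes a deliberate-leakage
canary (the target smuggled in as a feature drives out-of-fold RMSE to
near zero) to prove the harness *would* expose leakage if it existed.

Metrics per fold: RMSE, MAE, MAPE, R², and P(E &lt; 0.5) with a strict
inequality — the probability that a prediction misses by less than half a
score point. Summaries report the fold mean and SE, plus a 95% percentile
bootstrap interval computed by resampling the *pooled out-of-fold
predictions* and recomputing the metric per resample: ten fold-level values
are too few for stable percentile intervals, and sample-level resampling is
consistent with the narrow intervals such studies report. The comparison
table formats `mean (SE) (low–high)` per family and flags the best family
per metric. No pairwise significance tests between families are computed —
with hyperparameters independently re-selected in every fold, the paired
comparison a test would assume does not exist; rankings are descriptive.

## 7. Shapley attributions

Feature influence uses the interventional (marginal) value function:
`v(S)` is the mean prediction over background rows with the features in `S`
taken from the explained sample. This is well-defined without a density
model and matches common tree-attribution semantics; the conditional
variant would require modelling the feature distribution. Exact attribution
enumerates all `2^p` coalitions with Shapley kernel weights (feasible to
p = 12, used by the oracle tests); beyond that a permutation-walk sampler
draws one background row per permutation and accumulates prediction
increments, which is unbiased for the same value and reports a Monte-Carlo
SE per feature. Efficiency (`baseline + Σφ = prediction`) holds to 1e−9
for the exact method and exactly against the sampled baseline for the
sampler. The attribution model for reporting is the winning family refit
on the full dataset (the importance table reports one column per
algorithm, which implies full-data models), explained against a background
subsampled to at most 100 rows for cost.

## 8. Scaled-down budgets

Tests and the acceptance script must run on one CPU in minutes, so the
end-to-end checks shrink only the knobs that trade runtime for search
quality, never the stated cohort or validation structure: cohort size 419,
outer 10 / inner 5 folds, and seed-replication counts are kept; the ES
population is reduced (μ = λ = 6, generation cap 10) and the boosting box
narrowed (30–120 trees, depth ≤ 6). Package defaults remain the full-size
μ = λ = 30 configuration and the wide boxes.

## 9. Known limitations

* The synthetic world is statistical, not mechanistic: no Navier–Stokes
  solver, rigid quasi-steady analytic fields, no scanned-geometry
  ingestion. Conclusions about real cohorts require real CFD inputs.
* The wall-gradient (WSSG) definition operates on the time-averaged scalar;
  formulations based on instantaneous vector-component gradients would
  differ on strongly unsteady fields.
* SVR relies on a smooth approximation of the ε-insensitive loss; it is a
  faithful member of the pool but not a drop-in numerical replica of SMO
  solvers.
* Energy efficiency uses area-averaged speeds in the kinetic term — a
  consistent simplification across samples rather than a full kinetic-flux
  integral.
* The ICC assumes the two-way consistency model; pooling more than k
  raters into k columns requires an explicit mapping by the caller.
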