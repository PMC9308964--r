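---
title: "Quantile-based soil organic carbon storage potential: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-based soil organic carbon storage potential: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socpotential)
```

## The idea

Among places that share climate, terrain and land cover, observed soil organic
carbon (SOC) still varies widely. If the model accounts for the major soil
forming factors, much of the residual spread is plausibly management: the
upper conditional percentiles describe what comparable, well-managed soils
already hold. `socpotential` operationalizes this view:

1. predict conditional SOC percentiles (25th-95th) from mean annual
   temperature (MAT, degrees C), total annual precipitation (TAP, mm),
   elevation (m) and land cover;
2. take the median as the *current state*, the 75th percentile as an
   *achievable* target and the 90th as a *technical maximum*;
3. convert concentration gaps into areal carbon-stock gaps (the *additional
   storage potential*), and feed them to scenario arithmetic: 4-per-mille
   accumulation timelines, historical carbon debt under land-cover
   substitution, and sensitivity to projected climate.

Every stage is exercised on synthetic data with a fully known generating law,
so model recovery, calibration and accounting can be tested against analytic
oracles rather than against opaque reference numbers.

## The quantile network

`trainQuantileModel()` fits a fully-connected multi-task network: a shared
trunk of three hidden layers of 20 rectified-linear units and five linear
single-unit heads, one per percentile (25, 50, 75, 90, 95). Each head k is
trained under the pinball loss

$$L_\tau = \frac{1}{n}\sum_i \max\{\tau(y_i-\hat y_i),\,(\tau-1)(y_i-\hat y_i)\},$$

whose constant-prediction minimizer is the sample $\tau$-quantile; the total
loss is the sum of the five head losses. The outer heads (25th, 95th) are
co-trained regularizers only and are never consumed by the accounting
modules. Optimization is mini-batch Adam at the default hyperparameters
(100 epochs, batch 32, learning rate 0.001); 5% of the samples are held out
as a test set and the remainder is bootstrap-resampled into training and
out-of-bag validation rows. Continuous covariates are standardized with
means and standard deviations estimated *on the training rows only*; land
cover enters one-hot in the pooled mode, or selects one independent network
per group in the `per_landcover` mode (both modes are supported because
published descriptions of such models are ambiguous between them; the pooled
mode is the default since land-cover substitution scenarios need a model
that accepts a counterfactual land cover at fixed climate).

Numerical choices the fit depends on:

* **Quantile crossing.** Nothing in a multi-head network forces
  $\hat q_{25} \le \dots \le \hat q_{95}$. Predictions are sorted per
  location after the forward pass (the count of affected locations is
  attached to the result), then floored at 0% -- a physical bound.
* **Determinism.** The training loop (weight initialization, shuffling,
  bootstrap draws) runs off a self-contained Mersenne-Twister stream seeded
  from the training configuration, so a seed reproduces the fit exactly on a
  given platform.
* **Model selection.** With several bootstrap resamples, the fit with the
  lowest out-of-bag total loss wins; ties break by resample order. The
  default is a single resample: in our experiments the validation loss
  differences between resamples were well inside their noise, so extra
  resamples buy little at triple the cost.

## The synthetic soil landscape

`syntheticConfig()` fixes the generating law; its defaults are the package's
emulation of a global legacy soil database and are not tuned per analysis.
Covariates are uniform over MAT $\in$ [-10, 30] degrees C, TAP $\in$
[50, 3000] mm, elevation $\in$ [0, 3000] m; land cover is categorical over
cropland / pasture-natural / forest (probabilities 0.40/0.35/0.25). Log-SOC
is Gaussian:

$$\log y \sim N\!\big(\mu_0 + w^\top z(x) + \delta_{lc},\; (\sigma\, m_{lc})^2\big)$$

with $z(x)$ the covariates scaled to roughly $\pm 2$ over their ranges,
$w = (-0.4, +0.3, +0.1)$ for (MAT, TAP, elevation) -- carbon falls with
temperature through faster turnover, rises with moisture and (weakly) with
elevation -- $\mu_0 = \log 1.5$ so a mid-range cropland site has a median
near 1.5% SOC, and $\sigma = 0.5$ for a realistically right-skewed,
heteroscedastic distribution. Land cover acts twice: an additive offset
$\delta = (0, 0.25, 0.35)$ puts pasture and forest above cropland, and a
dispersion multiplier $m = (1, 1.1, 1.2)$ widens their upper tails, so the
land-cover influence grows toward the upper percentiles -- the qualitative
signature the attribution module is tested against. Because the law is
lognormal, every conditional quantile is closed-form
(`trueQuantile()`), giving the model tests an exact oracle.

Profiles expand each site value into layers by exponential depth decay
($k = 0.03$ per cm) whose layer means are exact integrals, with a layer
boundary pinned at 30 cm so the stored 0-30 cm truth is exactly recoverable.
Grids are low-frequency random surfaces rescaled into the covariate ranges,
with categorical fields thresholded to the configured class shares, and an
explicit per-cell area (default 0.25 km^2, a 500 m cell) -- areas are data,
not geodesy, to keep the accounting exactly testable.

What the generator does *not* emulate: spatial autocorrelation of SOC around
its conditional law, measurement-method heterogeneity, censoring or
preferential sampling of real soil surveys, and any real geography. Passing
tests therefore demonstrate that the machinery recovers a known law of this
shape, not that the real-world headline numbers are correct.

## Depth harmonization

Layered profiles are standardized to 0-30 cm with an equal-area smoothing
spline (`fitEqualAreaSpline()`): the minimizer of

$$\frac{1}{m}\sum_k (\bar f_k - y_k)^2 + \lambda \int f'(d)^2\,dd$$

over continuous, continuously differentiable piecewise quadratics on the
layer partition, where $\bar f_k$ is the fitted mean over layer k. The
quadratic family is not a restriction: the variational minimizer over all
smooth functions has constant second derivative within each layer, so the
exact solution is found by solving the KKT system of a small quadratic
program. As $\lambda \to 0$ the layer means of the fit converge to the
observations (the "equal-area" property); $\lambda$ defaults to 0.1, the
literature-standard smoothing weight for this family. $\lambda$ is floored
at $10^{-8}$ internally: the roughness penalty vanishes only on constants,
so the floor makes the program strictly convex and selects the constant
among otherwise-tied minimizers (a single-layer profile).

Depth conventions: intervals are half-open [top, bottom) cm measured
downward. Profiles whose deepest measurement is above `minDepth` (default
20 cm) are dropped from harmonization and counted; retained profiles
shallower than 30 cm are extended as a constant from the deepest layer
midpoint. Both rules are package decisions -- data-source papers rarely say
how shallow profiles were handled.

## Bulk density and stocks

Stocks need bulk density, which legacy data mostly lack. The package carries
the published rational pedotransfer function

$$BD(oc) = \frac{83.2687 - 0.011\,oc}{0.635\,oc + 52.847}
\quad \text{(oc in g kg}^{-1}\text{, BD in g cm}^{-3}),$$

monotone decreasing from 1.576 g cm^-3 at zero carbon, and can refit it from
(oc, BD) pairs. The rational form is invariant to a common scaling of its
four coefficients, so `fitPtf()` optimizes the d = 1 normalization
(nonlinear least squares, started from BD at the smallest oc, with five
seeded restarts) and reports that representative. Units cross the module
boundary once: percent SOC is multiplied by 10 to g/kg.

Cell stocks are $(oc/100) \times 1000\,BD \times 0.3$ kg C m^-2 for the
0-30 cm layer; zone totals are $\sum \text{stock} \times \text{area}
\times 10^{-6}$ Pg (1 kg m^-2 over 10^6 km^2 = 1 Pg, asserted by a unit
test). Bulk density is re-evaluated at each percentile's own concentration
-- the curve falls with carbon, so potential gaps in stock are tighter than
in concentration; a `fixedBd` switch supports sensitivity accounting.
Stocks are fixed-depth, with no equivalent-mass correction, matching the
framing of fixed 0-30 cm topsoil accounting. The packaged
`table1_ecoregions.csv` carries the published global-cropland stock table
(its 14 median entries re-sum to 82.66 Pg against a printed global 82.68 --
entry rounding, tolerated at 0.05 Pg in tests).

## Scenarios

*4-per-mille*: with a linear accumulation of $0.004\,s_0$ per year, the time
to a target $s_t$ is $(s_t/s_0 - 1)/0.004$ years; negative potentials are
clamped to 0 years and counted. The average capture rate is the potential
divided by the median years-to-target (this path reproduces the published
0.34 Pg C yr^-1 for the achievable potential; the alternative
$0.004 \times 82.68 = 0.33$ does not, so the former is the headline and both
are trivially computable).

*Historical debt*: cropland cells are re-predicted as pasture/natural at the
median and as forest at the 90th percentile; the two totals bound a debt
range whose midpoint is the headline debt. Totals use signed per-cell
differences by default (a `clipNegative` switch gives the positive-part
variant); the premise-based bound
$\text{debt} = C/(1-\text{loss}) - C$ at 25-75% loss is a separate,
closed-form path.

*Climate sensitivity*: the model is re-run with replaced MAT/TAP layers and
the percent change of the q50 stock and both potentials is reported. One
projected-climate pair per call; averaging over a GCM ensemble is the
caller's composition.

## Attribution

`shapleySample()` estimates Shapley values by permutation sampling: for each
sampled feature ordering and background row, features flip from background
to instance values in order and each feature is credited with the change in
prediction it causes. Defaults: 200 permutations per instance, background
subsampled to 100 rows. The estimator is unbiased for the interventional
Shapley value and satisfies local accuracy in expectation; tests compare it
to exact enumeration over all 16 coalitions of a 4-feature linear model and
check local accuracy within three Monte-Carlo standard errors. Percentile
comparisons use the percent change of mean absolute contributions between
heads; land cover is attributed as one categorical feature.

## Problem sizes and limitations

The test suite trains on 2,000-20,000 synthetic sites and predicts grids up
to 32 x 32; quantile-calibration checks use 20,000 training sites and a
fresh 20,000-site evaluation sample at three seeds -- sizes chosen so the
full suite runs in well under a minute on one CPU while keeping binomial
noise on coverage estimates near 0.003. Observed held-out coverage of the
75th/90th heads typically lands within ±0.03 of nominal, though individual
training runs can drift a few points further -- single-network quantile
calibration is noisy at these sample sizes, and no recalibration layer is
applied. Other known limitations: no spatial autocorrelation in the
generator (so map-level uncertainty is understated by construction), no
texture or other edaphic covariates, fixed-depth stocks, and linear-only
accumulation in the 4-per-mille scenario.
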