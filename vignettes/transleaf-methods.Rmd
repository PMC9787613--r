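---
title: "Trans-species leaf biomass estimation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-species leaf biomass estimation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transleaf)
```

## The model and its assumptions

`transleaf` estimates the oven-dry leaf mass `M_l` (kg) of an individual
tree from measurements that are cheap or already collected in forest
inventories, plus species-level published trait values. The working model is
ordinary least squares on the natural-log scale:

$$\ln M_l = \beta_0(CC) + \beta_1 \ln DBH + \beta_2 \ln LL + \beta_3 \ln LCR
  + \beta_4 \ln SG + \beta_5 \ln ST + \beta_6 \ln(MAT + 30)
  + \beta_7 \ln MAP + \varepsilon$$

The log-log form absorbs the strong heteroscedasticity of mass-size
allometries and makes power-law scaling linear. Its assumptions are the
usual ones: multiplicative lognormal error with constant log-scale variance,
independence across trees, and correctness of the additive log-linear
structure (no interactions; see below). The crown class `CC` — an ordinal
description of canopy position — enters as a *variable intercept*: five cell
means, one per class, with no global constant (`eq3`, the diameter-only
reduction, is the exception with a single intercept). Cell-means coding was
chosen because the published coefficient sets print five intercepts per
equation; it is numerically equivalent to reference-level coding plus a
constant and reproduces that parameterization directly. "Overtopped" and
"suppressed" are treated as one level (canonical label `overtopped`).

Species never enters as a factor. All species-level information flows
through three published trait values — leaf longevity `LL` (months), shade
tolerance `ST` (a 1–5 ordinal score), and wood specific gravity (`SG`
observed at breast height in `eq1`, or the published species average `SG_p`
in `eq2`) — which is what makes the model *trans-species*: a species with no
calibration data at all can be predicted as long as its traits are known.
The packaged trait table covers the 61 calibration species;
`attach_traits()` fails loudly, listing exactly the species for which trait
values must be supplied.

## Parameters that matter

* **`mat_offset` (default 30 °C).** `MAT` can be negative, so it is
  translated before the log. The offset is part of the model definition: a
  model fitted with one offset must predict with the same offset, so fitted
  and packaged models record it. Do not change it unless refitting from
  scratch.
* **`sigma2` and the Baskerville correction.** Naively exponentiating a
  log-scale prediction underestimates the conditional mean; predictions are
  multiplied by `exp(sigma2/2)`. For freshly fitted models `sigma2` is the
  unbiased residual mean square `RSS/(n - k)` (configurable to `RSS/n`); the
  convention is not fixed by the source material, and `RSS/(n-k)` matches
  both standard regression practice and the printed RMSE convention. The
  packaged coefficient sets print no residual variance, so they carry
  `sigma2 = RMSE^2` from the published fit-statistics table (0.50² = 0.25
  for `eq2`, giving the factor 1.133). That is an approximation — RMSE is
  the only printed dispersion — and is documented on the object itself.
* **AIC convention.** `aic = -2\,\ell + 2(k+1)` with the Gaussian constant
  and the variance counted as a parameter (identical to `stats::AIC` on an
  `lm`). The source software's convention is unknowable from the printed
  values, so only AIC *differences* between specs on the same data are
  treated as reproducible; the closed form
  `n log(RSS_A/RSS_B) + 2(k_A - k_B)` is tested.
* **MAAPE scale.** The printed formula for the arctangent metric carries a
  ×100 factor, but every printed MAAPE value (0.38–0.52) is consistent only
  with mean `atan(|p-a|/a)` in plain radians. `compute_metrics()` computes
  radians by default and offers `times_100 = TRUE`; the discrepancy is
  deliberate and documented rather than silently resolved.

## Cross-validation conventions

All three schemes share one engine: fit on the retained records, predict the
held-out unit with the Baskerville correction using *that training fit's*
residual variance (the source text does not say whether a global variance
was used; the training-fold choice is self-contained and honest about
out-of-sample uncertainty). Pooled metrics are computed over the union of
held-out pairs — tree-weighted, each record used exactly once — rather than
averaged over folds or species; this is the only convention under which a
single overall number and a per-species breakdown coexist coherently.
Per-species rows also report the signed mean error in kg as predicted minus
observed, consistent with "positive = overestimation". The k-fold partition
is a seeded uniform permutation cut into contiguous blocks, unstratified by
default (a stratify-by-crown-class flag exists); a training fold missing a
crown class present in its test fold is an error advising stratification,
because a cell mean cannot be extrapolated.

## Variable importance

Dominance analysis decomposes the model's plain R² into nonnegative
per-predictor contributions by averaging sequential-R² increments over
predictor orderings (LMG). The baseline is the constant-only model, and the
crown-class block participates as one group contributing its four indicator
degrees of freedom beyond the constant. This choice is forced by the fact
that the published importance figure assigns crown class its own share
(22.39%), which would be impossible if the class block were pure baseline;
whether the original computation handled the block identically is not
stated, so exact reproduction of the published shares is not claimed. With
up to 10 groups the exact subset-average identity is used (2¹⁰ subset R²
values); beyond that, orderings are sampled uniformly with a mandatory seed.

## Stepwise selection and VIF

Backward stepwise removes one whole term per iteration, choosing the removal
that most decreases AIC, stopping when none does; the intercept block is
structural and protected. Equal-AIC ties drop the term listed later in spec
order, deterministically. VIF on a cell-means design is ill-posed as
classically stated, so screening re-expresses the design with a constant and
four class dummies: continuous terms get the textbook `1/(1-R²_aux)`, the
class block the determinant-based generalized VIF on the
`(GVIF^{1/(2 df)})²` scale. Perfect collinearity reports `+Inf` rather than
erroring, since screening should describe pathology, not crash on it.

## What the synthetic generator does and does not emulate

`simulate_dataset()` draws trees from the *stated world* of the calibration
data: DBH lognormal moment-matched to the printed overall mean 23.01 cm and
SD 14.5 cm, truncated to the printed observed range (3.05, 114.05) cm by
inverse-CDF sampling; LCR as `0.1 + 0.9·Beta(2.44, 2.79)` (moment-matched to
mean 0.52, SD 0.18 on the printed (0.1, 1) range); site climate uniform
within the printed MAT (−0.4, 20.7) °C and MAP (275, 3084) mm ranges,
constant within each of 20 sites; species uniform over the packaged
61-species pool; observed SG scattered Normal(SD 0.05) around the published
value; crown class categorical with probabilities 0.05/0.2/0.4/0.2/0.15
(overtopped → open grown). The response is exactly the `eq2` linear
predictor (packaged published coefficients) plus Normal(0, σ = 0.50) noise —
the published log-scale RMSE. Where the source states no distribution (crown
class, species frequencies, climate covariance, the LCR–class dependence),
these are fixtures chosen once for realism, not claims.

Consequently a green test establishes correctness of the *procedures* —
estimation, correction, cross-validation accounting, importance decomposition
— under the model's own assumptions. It does not establish that real trees
follow `eq2`: the generator has no species-level residual effects, no
measurement error in DBH/LCR, no study-protocol heterogeneity, and uniform
species frequencies rather than the heavily unbalanced real sample. The
LOSO-equals-k-fold transferability property, in particular, is expected to
hold *by construction* on trait-driven synthetic data; on real data it is an
empirical finding.

An optional `contamination` fraction multiplies true leaf mass by
Uniform(0.2, 0.6) for a subset of "low-vigor" trees. This reproduces the
right-skewed percentage-error distribution (mean error well above the
median) that full-leaf-complement models show on real data when some sampled
trees carried fewer leaves than their size predicts — a mechanism check, not
an assertion about the actual cause.

## Numerical choices and degenerate inputs

Fitting uses QR least squares; rank deficiency is an error naming the
collinear columns, except that indicator columns for crown classes absent
from the data are silently not estimated (their cell means are undefined),
and predicting such a class later is an explicit error rather than an
extrapolated average. Predictions for DBH outside the model's training (or
published calibration) range warn but proceed. The significant-figure
inclusion filter operates on the as-read text tokens (trailing zeros count,
leading zeros do not; `"20"` has two significant figures), because recording
precision survives only in text; on binary numeric input it is a no-op with
a warning. All randomness (simulation, k-fold partitions, sampled orderings)
flows through explicit seeds and leaves the caller's RNG state untouched.

## Known limitations

* The packaged coefficient sets reproduce the published table verbatim,
  including one intercept (`eq6`, dominant, −9.110) that is inconsistent
  with its neighbours (−11.0 to −11.5) and is almost certainly a typo in the
  printed source; it is transcribed, not corrected.
* Printed per-species sample sizes disagree between the published summary
  and cross-validation tables, and the overall count is quoted both as 3628
  and 3901; the packaged trait table therefore records traits only.
* Climate must be supplied as `MAT`/`MAP` columns; raster extraction from
  coordinates, crown-ratio conversion models (compacted → uncompacted),
  interaction terms, and total-tree biomass are all out of scope.
* Exact reproduction of the published headline tables requires the deposited
  calibration dataset, which is not shipped; the test suite validates the
  machinery on synthetic data at the published noise level instead.
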