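---
title: "Methods: in-season wheat yield prediction from NDVI and agronomic traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-season wheat yield prediction from NDVI and agronomic traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldcast)
```

## The problem

Machine-harvesting thousands of experimental wheat plots to measure grain
yield (GY) is the single most expensive step of variety testing. Aerial NDVI
acquired at anthesis is a cheap proxy — NDVI tracks canopy biomass, and
biomass correlates with yield — but the proxy fails in two well-known ways:

1. **Saturation.** Over dense canopies NDVI stops responding to additional
   biomass, so in high-yielding material (above roughly 8 t/ha) plots with
   very different yields carry nearly the same NDVI.
2. **Harvest-index confounding.** Tall, high-biomass landraces carry NDVI as
   high as modern semi-dwarf varieties while yielding several t/ha less,
   because they partition far less biomass to grain.

`yieldcast` implements a calibration/validation pipeline that quantifies
both failure modes and tests whether adding cheap agronomic traits — days to
heading (DH), plant height (PH) and ear density (EARS) — to NDVI repairs the
prediction where NDVI alone saturates.

## The model space and the ridge engine

With four candidate traits there are $2^4 - 1 = 15$ non-empty predictor
subsets (`enumerate_models()`), fitted by ridge regression to stabilize the
fits under the strong collinearity among NDVI, PH and EARS. For a training
subset with standardized predictor matrix $Z$ (zero mean, unit *population*
standard deviation per column — the $1/n$ convention, pinned so that fits
are bit-reproducible) the coefficients minimize

$$\lVert y - \beta_0 - Z\beta \rVert^2 + \lambda \lVert \beta \rVert^2,$$

with the intercept unpenalized. The fit is closed-form via the singular
value decomposition; coefficients are reported back on the original trait
scale, so `predict()` consumes raw trait values. Fitted-value invariance
under affine changes of the predictors is property-tested.

**Penalty selection.** $\lambda$ is chosen by 10-fold cross-validation:
folds come from a seeded permutation (sizes differ by at most one), each
fold standardizes with its own training rows, and the selected $\lambda$
minimizes the held-out mean squared error with ties broken toward the larger
penalty. The default grid is 100 log-spaced values spanning
$[10^{-6} d_{\max}^2,\; 100\, d_{\max}^2]$, where $d_{\max}$ is the largest
singular value of the standardized design. The endpoints correspond to
shrinkage factors $d^2/(d^2+\lambda)$ from essentially 1 down to about 0.01,
so the grid can express anything from an OLS-like fit to an intercept-only
fit. (A grid anchored at $\max|Z^\top y|/n$, the lasso-style bound, is inert
under this penalty convention — its top end shrinks coefficients by less
than 1% at $n = 50$ — which is why the singular-value anchor is used.)
Under this grid a noiseless linear signal selects the smallest penalty and a
pure-noise response selects the largest in the majority of seeds, both
verified by simulation.

**Model complexity and BIC.** For a penalized fit the parameter count is
replaced by the effective degrees of freedom, the trace of the ridge hat
matrix:

$$\mathrm{edf}(\lambda) = \sum_i \frac{d_i^2}{d_i^2 + \lambda},$$

and models are compared by the Gaussian-likelihood BIC omitting additive
constants,

$$\mathrm{BIC} = n \ln(\mathrm{RSS}/n) + (\mathrm{edf} + 1)\ln n,$$

where the $+1$ counts the unpenalized intercept. At $\lambda = 0$ on a
full-rank design this reduces to the textbook BIC with $p + 1$ parameters.
Computing BIC on the ridge fit itself (rather than on an unpenalized refit
of each subset) keeps the complexity term consistent with the coefficients
actually used for prediction.

## Repeated-random-subset calibration and selection

For each training size (defaults 20, 50, 100) and each of the 15 subsets,
100 random training draws are fitted (`run_calibration()`). Two aggregation
choices were genuinely open and are resolved as follows:

* **Paired draws.** Within an iteration every subset is fitted on the *same*
  training plots, drawn from the plots complete for all candidate traits.
  This makes BIC differences between subsets paired comparisons and removes
  the sampling noise a per-subset draw would add.
* **Median aggregation.** The winning subset is the one with the lowest
  *median* BIC across iterations (the mean is also reported); the median is
  robust to the occasional ill-conditioned draw. Ties break toward fewer
  traits, then canonical order (NDVI, PH, DH, EARS). For an even number of
  runs the lower-middle order statistic is used, so the "median-BIC
  representative model" is always an actually fitted run — that run's model
  is the one carried forward to validation.

Training draws that leave a predictor with zero variance are redrawn with a
derived seed (at most 10 retries); a subset losing more than 20% of its
iterations aborts the ensemble with a diagnostic. Plots missing any trait of
a given subset are excluded from that subset's fits (listwise per-model
deletion) — the source tables do not prescribe a missing-data rule, and
per-model deletion maximizes usable plots; exclusion counts are reported.

## Validation and the NDVI benchmark

Representative models predict the held-out plots; accuracy is the squared
Pearson correlation between observed and predicted yield (with the t-test
p-value on $n-2$ df, floored at $10^{-15}$), error is the RMSE in t/ha, and
the observed-on-predicted OLS line is reported for 1:1 plots. Every report
pairs the best multivariate model with the NDVI-only model fitted in the
same ensemble — the benchmark is simply the $p = 1$ case of the same ridge
pipeline, keeping the comparison uniform. Relative differences follow the
convention $100\,(x_\mathrm{best} - x_\mathrm{NDVI})/x_\mathrm{NDVI}$ for
both $R^2$ and RMSE.

## Saturation analysis and heritability

`stratify_by_yield()` cuts a table at a yield threshold (default 8 t/ha;
plots exactly at the threshold go to the "above" stratum — either convention
works, this one is pinned and tested) and `saturation_scan()` reports the
NDVI-yield $R^2$ within each stratum, flagging strata with fewer than three
plots as insufficient rather than failing. The pipeline's stratified mode
fits entirely separate calibration ensembles below and above the threshold.

Broad-sense heritability uses the balanced one-way ANOVA method of moments:
$\hat\sigma^2_e$ is the within-genotype mean square,
$\hat\sigma^2_g = (\mathrm{MS_G} - \mathrm{MS_E})/r$ truncated at zero, and

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_e / r}.$$

Unbalanced replication is an error by design: the formula presumes a single
replicate count, and silently approximating it (or importing REML machinery)
would change the estimand. With few genotypes the plug-in $H^2$ estimate is
noticeably biased downward (the inverse mean-square ratio is skewed), so
recovery checks pool variance components across simulated trials before
forming $H^2$.

## The synthetic trial generator

No plot-level data are distributed with the trial structures this package
emulates, so every pipeline stage is exercised on synthetic tables
(`generate_trial()`). The generator is a minimal mechanistic model of the
two study designs:

* **Yield.** Per experiment-by-class cell, genotype effects
  $g_i \sim N(0, \sigma^2_g)$ and plot errors $N(0, \sigma^2_e)$ around the
  cell mean, floored at 0.1 t/ha. For replicated cells the two components
  are derived from the cell's phenotypic SD and target $H^2$ as
  $\sigma^2_g = H^2\,\mathrm{sd}^2 / (r(1 - H^2) + H^2)$, so a balanced
  trial with $r$ replicates reproduces both moments and heritability;
  non-replicated cells split the variance evenly.
* **Agronomic traits.** (DH, PH, EARS) are drawn jointly with yield from a
  Gaussian copula with correlations (GY-DH $-0.60$, GY-PH $0.70$, GY-EARS
  $0.70$) whose magnitudes mirror published trait-yield $R^2$ values of
  roughly 0.36/0.51/0.49; printed $R^2$ carries no sign, so directions are
  configurable, with defaults set to the agronomically expected pattern
  (later heading penalized in a terminal-drought environment, height and
  ear density rewarded within modern germplasm). Means/SDs default to DH
  140 ± 6 days (late-November/December sowing, mid-April anthesis), PH 85 ±
  12 cm, EARS 450 ± 80 ears/m²; landraces head ~5 days later, stand ~25 cm
  taller and tiller less densely.
* **NDVI.** Canopy biomass is `gy / harvest_index` (landrace 0.33, modern
  0.48) and NDVI follows the Beer-Lambert-like response
  $0.15 + (0.92 - 0.15)(1 - e^{-k\,\mathrm{biomass}})$ with $k = 0.15$ per
  t/ha, plus $N(0, 0.04)$ measurement noise, clipped to $[0,1]$. The curve
  parameters were set once so that the two published qualitative patterns
  emerge: landrace and modern canopies differ by less than 0.05 NDVI while
  yields differ by over 4 t/ha, and the NDVI-yield $R^2$ collapses above
  8 t/ha while staying strong below it. Setting
  `saturation_enabled = FALSE` swaps in an affine NDVI-biomass map, which
  removes the stratified contrast — the negative control used in tests.

**What the generator does not emulate:** spatial field trends, weather and
phenology dynamics, genotype-by-environment interaction, genotype structure
in the non-yield traits (they co-vary with yield at the plot level only),
and the pixel-to-plot image processing upstream of plot-mean reflectances.
Passing tests therefore demonstrate that the pipeline's estimators and
selection machinery behave correctly under the structure the analysis
assumes — not that any particular accuracy level will be attained on real
field data, whose headline values cannot be reproduced without the
undistributed raw plots.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run the full default case study
(348 plots, 15 subsets x 100 iterations x 3 training sizes x 2 strata,
~1 minute on one core) and reduced Monte-Carlo designs elsewhere (e.g. 50
master seeds for selection consistency, 200 simulated trials for
heritability recovery) — sizes chosen to keep the whole suite comfortably
reproducible on a laptop while leaving Monte-Carlo error well inside the
asserted tolerances. Other pinned conventions: population (1/n) variance for
standardization; CSV with empty cells for absent values and 17-significant-
digit numerics so tables round-trip exactly; dates accepted as ISO-8601 or
dd/mm/yyyy; all child seeds derived deterministically from one master seed.

## Known limitations

* Exhaustive subset search is guarded at 10 candidate traits.
* Heritability handles balanced designs only, and only replicated trials.
* The NDVI benchmark and all models are linear in the traits; no
  nonlinear index transforms or neural alternatives are provided.
* The generator's Gaussian copula cannot represent tail dependence or
  threshold-like trait relationships.
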