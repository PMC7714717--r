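---
title: "Models and methods behind phenopipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenopipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenopipe processes plot-level trait time series from outdoor
high-throughput phenotyping platforms — daily canopy traits such as 3D leaf
area (mm²), projected leaf area (mm²) or plant height (cm) measured on
hundreds of genotypes laid out in an alpha design — and turns them into
genotype adjusted-mean (G-BLUE) and heritability time series, then into
growth-phase summaries. This vignette documents the statistical models, the
defaults and the numerical choices, so that every tunable parameter has a
stated reason.

## Stage 1: preprocessing

**Outlier masking.** Measurements from outdoor platforms occasionally fail
(wind, animals, transmission errors), producing extreme values. For each day
separately, the distribution of all plot values is summarised by its
quartiles (linear-interpolation convention, quantile type 7; the common
default and a deliberate, documented choice since several conventions
exist), and values strictly below `Q1 - 1.5 IQR` or strictly above
`Q3 + 1.5 IQR` are replaced by missing values. Strict inequalities mean a
constant day flags nothing. The rule is applied across all genotypes
jointly, which assumes the genotype spread within a day is modest compared
with the fault magnitude; for traits with extreme genotype ranges a per-group
rule could be preferable (not implemented).

**Predictive mean matching (PMM).** Missing values of day *i* are imputed
from all other days, which carry the growth-trend information: a linear
regression of day *i* on the other days is fitted over the rows where day
*i* is observed, coefficients are drawn from their sampling distribution
(residual variance from a scaled inverse chi-square with the residual
degrees of freedom, then a Gaussian draw centred at the estimates with
covariance `sigma^2 (X'X + lambda I)^-1`), every row is predicted, and each
missing cell receives the *observed* value of one of the `k = 5` donors
whose predictions are closest to its own. Drawing observed values keeps
imputations inside the trait's empirical support, which is why outlier
masking before imputation matters: it restricts the donor pool to credible
values.

Numerical choices:

* Predictors are standardised and the regression is stabilised with a fixed
  ridge penalty of `1e-5` on the standardised predictors (not the
  intercept), so collinear day pairs can never make the solve fail. The
  penalty is orders of magnitude below the signal and acts only as a
  tie-break.
* Predictor cells that are themselves missing are filled with their day's
  observed mean for the single sweep. A full chained-equations loop is out
  of scope by design; with moderate missingness the mean-fill mainly
  attenuates predictions uniformly, which leaves the donor *ranking* — the
  only thing PMM uses — largely intact. This is also why strict
  complete-case fitting is not used: under 50% missingness spread over ~22
  days, complete rows essentially never exist.
* `m = 5` imputations are pooled by cell-wise means. The downstream mixed
  models need a single completed matrix; between-imputation variance is not
  propagated, so classical multiple-imputation pooling rules would buy
  nothing here.
* Days with more than 75% missing cells are refused with guidance, as the
  donor pool becomes too thin for matching.
* The random-draw protocol (one chi-square draw, one Gaussian vector, one
  donor draw per missing cell in row order; days in column order;
  imputations outermost) is documented in `?impute_pmm` and frozen by a
  test against an independently coded step-by-step reference.

## Stage 2: the daily spatial mixed model

For each day the model is

y = mu + replicate + block(replicate) + row + col + f(row, col) + genotype + e,

with replicate, block-within-replicate, row and column as independent random
effects and `e ~ N(0, sigma_e^2)`. The smooth surface `f(row, col)` is a
two-dimensional penalised tensor-product B-spline in its PS-ANOVA mixed-model
form: fixed linear trends in rows, columns and their product, plus five
random blocks — smooth row, smooth column, linear-by-smooth in both
directions, and smooth-by-smooth — each with its own variance. Each marginal
basis is eigen-transformed so that its difference penalty becomes an
identity, which turns every spline block into an iid random effect.

* **Genotype fixed** (sum-to-zero contrasts) yields the G-BLUEs, reported as
  intercept plus effect with standard errors from the coefficient precision
  matrix.
* **Genotype random** yields the heritability. Without the spatial term,
  `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`. With it, the classical formula
  is no longer well defined at plot level and the effective-dimension form
  is used: `h2 = ED_g / (n_g - l)`, where `ED_g` is the trace of the
  genotype block of the hat matrix and `l` the number of zero eigenvalues of
  that block (computed from the spectrum of the centred genotype
  cross-product, not assumed; it is 1 whenever all genotypes are observed
  and an intercept is present).

**Estimation.** REML by Schall iterations: given current variance ratios,
solve the penalised least-squares system, update each block variance by
`u_b'u_b / ED_b` with `ED_b = q_b - lambda_b tr(C^-1_bb)`, and the residual
variance by `RSS / (n - ED_model)`. Numerical choices:

* B-spline bases: cubic, second-order difference penalty, with
  `nseg = max(5, min(ceiling(n/2), 12))` segments per dimension. The cap at
  12 keeps the coefficient count near 700 on a 48 x 32 grid instead of
  ~1030; platform surfaces (heat gradients along walls, irrigation trends)
  are smooth at the scale of several plots, and in simulations with planted
  smooth surfaces the capped basis recovers them while fitting in a third
  of the time. Both the cap and all basis settings are arguments.
* Convergence is declared when the maximum relative change of the variance
  components falls below `1e-6` *or* the REML deviance (computed from the
  Cholesky factor at no extra cost) stabilises to `1e-7` relative. The
  second criterion matters because boundary components decay geometrically
  toward zero: they stall the component criterion for hundreds of
  iterations while the restricted likelihood — and the fit — no longer
  moves.
* Variance components are floored at `1e-10`; components falling below
  `1e-8` of the response variance are snapped to the floor directly (their
  decay is geometric and their contribution already nil). Floored
  components are recorded in the fit.
* Initialisation puts most of the variance on the residual
  (`sigma_e^2 = var(y)`, block variances `var(y) / (2 n_blocks)`). An
  over-flexible start can push the total effective dimension to `n`,
  collapse the residual degrees of freedom and drive the system toward a
  singular interpolating fit; the conservative start avoids that regime.
  Warm starts between consecutive days reuse the previous day's components,
  except floored ones, which restart from the default (a floored component
  has an effectively infinite penalty and could never re-emerge).
* After convergence one final solve at the converged components makes the
  reported coefficients, effective dimensions and variances mutually
  consistent; a test checks the solution against a dense GLS solve at those
  components to `1e-6`.
* Genotypes with no observation on a day get no adjusted mean for that day
  (no extrapolation); they are recorded and excluded from downstream
  correlations for that day.

**Single-step cleaning (S9).** As an alternative to preprocessing, the model
is fitted and the two-sided Grubbs statistic `max |r - mean(r)| / sd(r)` is
applied to the residuals; while significant at `alpha = 0.05` (t-based
critical value) the most extreme observation is dropped and the model
refitted, up to 2% of the observations (the test is one-at-a-time by
construction, and the cap bounds the cost of pathological days). Degenerate
residual spreads stop the loop cleanly.

## Processing strategies

S1–S8 are the eight on/off combinations of outlier masking, imputation and
spatial adjustment; S9 is the single-step variant. The G-BLUE series always
comes from genotype-fixed fits; the daily heritability series requires a
second, genotype-random fit per day — the package always runs both when the
`h2` series is requested and shares warm starts to halve the cost. Days
whose fit fails are recorded as missing rather than aborting a series.

## Stage 3: temporal analysis

**Logistic growth fits.** Each genotype's G-BLUE series is summarised by
`A / (1 + exp(-k (t - t0)))` fitted by bounded Levenberg–Marquardt least
squares (`A > 0`, `k > 0`; a three-parameter form — senescence or segmented
models are out of scope). Starting values: `A0` the series maximum, `t0` the
day of half-maximum, `k0` the log-linear slope between 20% and 80% of `A0`.
Goodness of fit is `R2 = 1 - SSres/SStot`; non-convergent fits are flagged
and excluded from averages.

**Clustering and Clust-Dist.** Whole-series genotype vectors are clustered
by kernel k-means under a Gaussian kernel; the bandwidth defaults to the
median pairwise distance (recorded in the output). The cluster count is
chosen by the mean silhouette over a candidate range, computed on Euclidean
distances of the raw series for interpretability (configurable); ties take
the smallest k, and a maximum below 0.25 is flagged as low-confidence.
Emptied clusters are reseeded with a random point (at most 10 times), and
several seeded restarts keep the within-cluster kernel dispersion at its
minimum — on eight-genotype instances a test checks the exhaustive-partition
optimum. The expressed-diversity series (Clust-Dist) is the mean pairwise
Euclidean distance between cluster centers per day, which reduces to
`|c1 - c2|` for two clusters; the mean-pairwise generalisation for `k > 2`
is a package choice.

**Change points and the optimal time window.** The day-wise pair
(heritability, Clust-Dist) is segmented by divisive hierarchical
change-point detection with the energy statistic and within-segment
permutation tests. The two variables live on scales that differ by orders
of magnitude, so the columns are z-scored first; a test asserts the output
is invariant to affine rescaling of either input. Defaults: `min_size = 3`
(a ~22-day series cannot support larger minimum segments), `n_perm = 199`,
`alpha = 0.05`. The optimal time window (OTW) is selected by a codified
rule: among interior windows with non-negative Clust-Dist slope (diversity
still expanding), take the one with the highest median heritability; fall
back to the global median-h² maximiser, and with two windows take the
higher-median one. The window summary and the rule actually used are always
returned, because window choice is ultimately a judgement call that the rule
only codifies.

**Cluster-by-window ANOVA.** Genotypes are grouped into three vigor classes
by k-means on their mean G-BLUEs inside the OTW (labels ordered by center),
and the genotype-by-window mean G-BLUEs are partitioned by a sequential
(Type I) two-way ANOVA fitted in the order cluster, window, interaction.
Sequential sums of squares are a deliberate choice — the genotype-by-window
table is balanced by construction (every genotype contributes one mean per
window), where Type I and Type III coincide; `SS% = 100 SS / total SS`
including the residual row.

## Validation machinery

**Cross validation.** Ten replications of five-fold CV; each replication
draws one day at random to cover the time dimension, partitions that day's
observed plots into five folds, and holds each fold out in turn.
Preprocessing is applied with the held-out cells masked, so no information
leaks from the validation cells; validation plots are predicted from their
design row (genotype estimate plus replicate/block/row/column effects and
the surface at their coordinates — positions are fixed, only the response is
held out). All strategies see identical partitions, and treatment contrasts
(outlier masking on/off, imputation on/off, spatial on/off) are paired
per (replication, fold) before the t-test.

**Between-experiment correlation** pairs two trials on the same panel day by
day and correlates G-BLUEs over the genotypes observed in both (days with
fewer than three common genotypes are skipped and logged).

**Robustness simulation.** G-BLUEs of a clean reference day are computed
once with the spatial model (the same model S5 uses — the natural reference
since contamination responses are measured against it), then the *whole
series* is contaminated (missing cells and/or additive `N(0, 3 Var(day))`
noise on a fraction x of cells; imputation-based strategies need the whole
series, so contaminating only the reference day would leave them untested),
each strategy is rerun, and the reference-day G-BLUEs are correlated with
the reference. Missing and noise cell sets are drawn independently in the
combined scenario. Injection selections are keyed on plot and day labels,
making them equivariant under plot reordering.

## The synthetic trial generator

The generator emulates a large outdoor laser-scanner screen: an alpha design
(by default
384 genotypes x 4 replicates, 12 blocks per replicate, a 48 x 32 plot grid),
genotype-specific three-parameter logistic growth curves (defaults:
asymptote 60–120 cm, rate 0.25–0.55 per day, inflection days 8–15 over 22
days — plant-height-like), static replicate/block/row/column effects, a
smooth spatial surface (low-order polynomial plus a Gaussian ridge along one
wall, mimicking wall-heat gradients; amplitude defaults to 0.3 genotype
standard deviations, and the design-effect standard deviations to 0.10–0.15),
and iid Gaussian error. The error standard deviation is scaled per day so
the plot-level heritability equals the target (0.7 by default) every day:
genotype spread grows with the curves, and a proportional error keeps the
signal-to-noise ratio — the quantity that drives every downstream result —
constant across the series, mirroring the multiplicative error of optical
canopy measurements. A method-of-moments one-way ANOVA on a mid-series day
of the full-size trial recovers the target within the band checked by the
tests (the ANOVA error also absorbs the design and spatial variance, so its
estimate sits slightly below the target).

The generator deliberately does **not** emulate scanner physics, canopy
overlap between neighbouring plots (the mechanism behind late-season
resolution loss on real platforms), missing-not-at-random patterns, or
senescence-driven trait decline. Passing tests therefore demonstrate that
the pipeline recovers known signal under realistic *MCAR/outlier*
contamination on smooth growth — not that it corrects the structured
artefacts of any particular sensor.

## Problem sizes

The test suite exercises trials from 20 to 384 plots (with one full-size
384-genotype design for generator checks), keeping the default run within a
couple of minutes. The acceptance study (`scripts/acceptance.R`) uses the
full 384-genotype, 4-replicate, 22-day trial with ten repeats per
contamination cell — the size at which variance-ratio estimates and
correlation summaries are stable to the second decimal.

## Known limitations

* The PMM sweep is single-pass; under extreme (>50%) missingness a chained
  loop would impute better.
* The ANOVA-based heritability of the generator calibration and the
  effective-dimension heritability of the spatial model are related but not
  identical quantities; comparisons across the two should be qualitative.
* Grubbs cleaning removes one observation per refit and is capped; days
  with massive contamination are better served by the preprocessing path
  (S8), which is also what the robustness study shows.
* The e-divisive permutation test is exchangeability-based; strong
  autocorrelation within segments would inflate detections.
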