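---
title: "Forecasting microbial abundances and detecting community shifts"
author: "microShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting microbial abundances and detecting community shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microShift)
```

## The problem

Microbial communities — the human gut microbiome, the influent of a
wastewater treatment plant — fluctuate strongly from sample to sample
even in perfectly healthy or stable conditions. An early-warning system
must therefore not ask "did genus X change?" but "did genus X change
*more than its normal variability allows*?". microShift answers this by
learning each community's normal dynamics from a longitudinal
genus-level feature table, forecasting every genus one step ahead, and
flagging observations that escape an ensemble-based prediction
interval.

## The model

### Data contract

An `AbundanceSeries` wraps a `SummarizedExperiment`: genera as rows,
samples as columns, a `counts` assay of non-negative abundances, and
column data carrying the canonical integer time step, the original
timestamp, subject/site identity, an optional sick-day flag and numeric
covariates. Timestamps are ISO dates or plain integers; they are mapped
to integer steps in observation order. Missing time points are absent
columns — the pipeline deliberately does not interpolate or resample,
because imputing microbial time series is an unsolved problem and the
models are trained on the observed sequence as ordered.

When several subjects or sites are combined, `harmonizeGenera()`
re-indexes all tables on the union of observed genera (plus optional
roster supplements, e.g. baseline gut taxa or sepsis-associated
genera); a genus absent from one subject but present in others is
assigned zero abundance. Genus matching is exact string match after
whitespace trimming — taxonomy-aware merging is out of scope, so
upstream tables should come from one classifier and reference release.

### Scaling, splitting, windowing

Each genus is min–max scaled to [0, 1]. Two choices here are genuinely
open and we fix them as follows:

* **Per-genus scaling.** "All inputs transformed equally" is read as
  *the same rule for every genus*, i.e. the conventional feature-wise
  scaler, not a single global min/max. A global scaler would crush
  low-abundance genera into a numerically invisible band, defeating
  per-genus intervals.
* **Train-only fitting.** The scaler is fitted on the training
  partition only. Fitting on all data would leak the test range into
  the transform and silently shrink out-of-range test observations —
  exactly the observations the outlier detector must see. For the same
  reason scaled test values outside [0, 1] are *never clipped*.
  Constant (degenerate) genera — typically zero-filled absences — map
  to 0 under the forward transform and return their constant under the
  inverse.

The series is split chronologically: the first 80% of samples form
train+validation (the final 10% of that block is validation for early
stopping; both fractions configurable), the last 20% is test. No
shuffling — shuffled splits would leak future states into training.
Windows then pair each target row with its `lag = 3` preceding rows
over all genera plus any configured covariates; with horizon 1 a
partition of length T yields exactly T − lag windows. Validation and
test windows take their lag context from the immediately preceding
rows of the full series, so every held-out row is a prediction target.

### Forecasters

One multivariate model per dataset maps the lag window to the next
abundance vector of all genera jointly. A joint model (rather than one
model per genus) is required for input-importance analysis across
genera and lets the model exploit cross-genus structure.

* **Recurrent networks** (LSTM, GRU): single recurrent layer, ReLU cell
  activation, linear dense output of width G, MAE loss on the genus
  outputs only (covariates are inputs, never targets), Adam optimizer,
  inverted dropout on the recurrent output (default rate 0.2), early
  stopping on validation MAE (default patience 10). The implementation
  is native R: with sequences of length 3, exact backpropagation
  through time is a few small matrix products, and full-batch Adam
  converges in a couple of hundred epochs on the series sizes this
  package targets. The published architecture width is 2048 cells; for
  a few hundred time points a 32-cell layer is the practical default —
  wider layers mostly buy training-set memorization (see the overfit
  diagnostic). Fits are deterministic given the configuration seed
  under single-threaded execution.
* **Random forest**: the lag window flattened to lag × width features,
  one 100-tree `ranger` regression forest per output genus, seeded and
  single-threaded for determinism. The forests split on variance;
  the mean-absolute-error split criterion that scikit-learn exposes is
  not available in R forest implementations, so the configuration
  records the criterion label for provenance while the fit uses
  variance splitting. In practice the two criteria rank splits almost
  identically on these data sizes.
* **VARMA baseline**: per-column Dickey–Fuller unit-root test at
  α = 0.05 (plain, lags = 0 by default; augmentation lags available),
  one round of first-order differencing if any column is
  non-stationary, then (p, q) selected from a grid (default 0..3 each)
  by AIC using Hannan–Rissanen two-stage estimation: a long VAR
  supplies innovation estimates, each candidate order is an OLS
  regression of the current vector on lagged values and lagged
  innovations over a common effective sample, and AIC =
  log det Σ̂ + 2k/n. Ties break toward the smaller p + q. The trend
  term (none / constant / linear time) enters the stage-2 regression;
  forecasts on a differenced fit are integrated back. Critical values
  for the unit-root tau statistic use the MacKinnon response surface;
  the statistic agrees with reference implementations to numerical
  precision.

Two forecasting modes exist and are kept strictly separate:
**teacher-forced** one-step-ahead prediction conditions each step on
the *observed* recent past and is the default for outlier detection —
an early warning must compare today's observation against what the
healthy dynamics predicted from the actual recent history. **Iterative**
multi-step prediction feeds its own outputs back into the window and is
used for trajectory extrapolation plots.

### The prediction interval

N models of identical architecture are trained with distinct seeds
(default N = 50, derived from one global seed via an FNV-1a hash of
(seed, component, member index)). At each time point and genus the
interval is

    mean ± z · sd        (sample sd over members, ddof = 1;
                          z = 1.959964 for 95% coverage)

computed in scaled space and back-transformed through the monotone
affine scaler — by linearity this equals the interval computed from
back-transformed members, and a property test asserts it. Where the
convention was unstated we chose the sample standard deviation
(ddof = 1) and the exact normal quantile rather than rounded 1.96;
hand-check examples use 1.96.

An observation strictly outside the bounds is an outlier; values equal
to a bound are not. Missing observation rows are skipped and logged,
never flagged. Degenerate genera have point intervals, so *any*
deviation flags — intentional: a genus that was identically zero
throughout training and suddenly appears is exactly what a monitor
must report.

**What the interval measures — and what it does not.** The spread of an
ensemble whose members differ only by seed quantifies *model*
uncertainty (initialization, dropout, bagging), not observation noise.
No noise term is added. Consequently the interval under-covers by
construction on noise-dominated data: when innovation noise dwarfs
model variance, far more than 5% of healthy observations fall outside.
This is documented behaviour, not a defect to be patched away: the
method is designed for communities whose dynamics are largely
learnable, and the calibration property below makes the assumption
precise.

### Evaluation

MAE and RMSE are computed on the absolute-abundance scale after
back-transform (a scaled-space mode exists for debugging), pooled over
all (time, genus) cells and per genus. NRMSE divides the RMSE by the
standard deviation *of the predicted values* — an unusual but here
contractual convention that makes errors comparable across genera of
very different abundance and is invariant to common affine rescaling;
constant predictions make it undefined and return `NA` with a warning,
never infinity. The overfit diagnostic flags a fit when test/train
exceeds 3 for MAE or RMSE; a stricter factor-2 convention is
occasionally used, so the threshold is configurable and defaults to 3.
Whether pooled or genus-averaged aggregation is intended in published
tables is ambiguous; we pool over all cells by default.

### Networks and importance

`buildNetwork()` tests all genus pairs with Spearman (default), Pearson
or Kendall correlation, retains edges with |ρ| ≥ 0.6 (the conventional
threshold for co-occurrence networks) *and* BH-adjusted q ≤ 0.05 — the
FDR criterion is standard practice on top of the magnitude convention
and can be disabled — and drops genera without any retained edge.
Hub ("keystone") genera are ranked by degree and by summed |ρ|
(strength), ties broken lexicographically. The native importance
provider permutes one genus's lag columns across windows and measures
the MAE inflation (seeded, averaged over repeats; constant features
score 0 by definition); an externally computed Shapley-value table can
be loaded instead, ranked by absolute score with direction retained.
SparCC is not implemented. `compareRankings()` reports top-k sets and
Jaccard overlaps between importance and hub rankings.

## The synthetic generator

`generateSeries()` draws, per genus,

    x_t = baseline + amplitude · sin(2π t / period + phase) + s_t,
    s_t = φ · s_{t−1} + ε_t,   ε_t ~ N(0, noise_sd²),

then rounds to non-negative integer counts (optional dispersion jitter
and zero-inflation masking), applies shift events *after* the noise
draw — so the ground-truth labels are unambiguous — and drops whole
rows to emulate missing samples. Counts via a rounded Gaussian latent
rather than negative-binomial sampling keep event magnitudes
interpretable in σ units; the dispersion knob adds Poisson-like jitter
when count-type noise is wanted. Regeneration from the same truth
object is bit-identical.

What it emulates: seasonality, autocorrelation, heteroscedastic noise
(noise scales with baseline in the presets), zero-inflation, row-wise
gaps, covariates (seasonal temperature, skewed non-negative
precipitation), and labelled spike / level-shift / dropout events. What
it does not: compositional coupling between genera, taxonomic
structure, sequencing-depth variation, or batch effects — so a passing
test shows the *method* behaves as designed, not that any particular
real community is predictable.

### Scenario presets and their parameters

* `gut_dense` — 20 genera, T = 396 dense time points, no covariates.
  Baselines are log-normal (median ≈ 300 counts, one order of magnitude
  spread), seasonal amplitude 25% of baseline with period 30 steps,
  AR(1) coefficient φ = 0.4, innovation sd 15% of baseline, mild
  zero-inflation for rare genera. The weak day-to-day persistence
  reflects how strongly dense human-gut series fluctuate between
  consecutive samples; it is also what gives a learned forecaster its
  edge over last-value persistence (for an AR(1) deviation process the
  one-step error variance of persistence is 2(1−φ)σ², against
  (1−φ²)σ² for the conditional mean).
* `wastewater_monthly_gappy` — 15 genera, six years of monthly samples,
  annual cycle (period 12), temperature and precipitation covariates,
  and every December–February missing, mirroring monitoring programmes
  that skip winter sampling.
* `wastewater_weekly` — 15 genera, two years of weekly samples, annual
  cycle (period 52), covariates, 5% random row missingness.

### The spike-recovery scenario

Detector behaviour is assessed in the regime the interval's assumption
holds: *model-uncertainty-dominated* data. The scenario uses 10 genera
over T = 150 steps with deterministic seasonal + AR structure and zero
innovation noise — integer rounding is the only measurement noise — so
the ensemble spread (here: bagging variability of 100-tree forests) is
the dominant uncertainty, and the 95% interval operates near its
nominal level (clean false-flag rate ≈ 8% with a 10-member ensemble).
Spikes are multiplicative factor-3 events, which exceed five temporal
standard deviations of every genus; all are recovered. On
noise-dominated data (innovation sd ≥ 0.5% of baseline in this
scenario's geometry) the same ensemble's spread is an order of
magnitude smaller than the prediction error and the false-flag rate
rises far above nominal — the under-coverage documented above, shown
quantitatively by the calibration property: when members and the
observation are i.i.d. draws from the same normal law (model variance
= predictive variance), the flag rate over 10,000 cells sits between
3.5% and 6.5%.

## Numerical choices

* Min–max inverse is exact on non-degenerate genera (round-trip error
  < 1e−9 asserted); degenerate genera return their constant.
* AIC ties in the VARMA grid go to the smaller p + q (then smaller p):
  the grid is evaluated in that order and the first minimum wins.
* Ill-conditioned VARMA fits drop the lowest-variance genus with a
  warning and retry; an exhausted grid is an error.
* Early stopping restores the best-validation weights; with no
  validation set it is disabled with a warning.
* Sub-seeds derive from (global seed, component, index) via FNV-1a mod
  2³¹, keeping every derived seed a valid 32-bit R integer.
* The forget-gate bias of the LSTM initializes to 1; other weights are
  Glorot-uniform.
* `NaN` anywhere in training windows, member forecasts or prediction
  inputs is an error naming the offending member/cell, never silently
  propagated.

## Problem sizes used by the test suite

The suite exercises the full pipeline at sizes chosen to make every
statistical assertion sharp yet quick: the dense gut preset at its full
G = 20 × T = 396 for forecaster skill (5 seeds, RF and a 32-cell LSTM
against persistence), 10-member RF ensembles on the T = 150
spike-recovery scenario (5 spike seeds + 5 clean seeds), 10,000-cell
interval calibration, 200 unit-root replicates at T = 500, 100 MA(1)
grid-search replicates at T = 300, and 100 null-network replicates at
n = 100 × 20 genera.

## Known limitations

* The interval quantifies inter-model variance only; see above. A
  conformal or quantile-regression interval would cover observation
  noise but is a different method, deliberately out of scope.
* No multiple-testing correction across genus × time cells in outlier
  detection; at 95% coverage one expects ~5% flags on healthy
  model-dominated data, and users monitoring many genera should read
  single isolated flags accordingly.
* Abundances are modelled on the absolute scale; compositional
  transforms (CLR/ILR), rarefaction and imputation are out of scope.
* The random-forest backend cannot use an MAE split criterion (not
  offered by R implementations); variance splitting is used and
  recorded.
* VARMA estimation is conditional least squares (Hannan–Rissanen), not
  exact maximum likelihood; for order selection and baseline forecasts
  on a few hundred time points the difference is immaterial, but the
  fitted coefficients are not MLE.
* Recurrent training is full-batch; for series beyond a few thousand
  windows mini-batching would be preferable.
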