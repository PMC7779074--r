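---
title: "Localized versus distributed cortical processing: models, parameters and design choices"
author: "cortexflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized versus distributed cortical processing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexflow)
```

# The scientific question and the measurements

Cortical regions differ in how they participate in tasks. A region can
process information *locally* — visible as strong task-evoked activation —
or *distributedly* — visible as its functional connectivity (FC) with the
rest of cortex. `cortexflow` quantifies both per region and relates them to
three task-free descriptions of cortical hierarchy: a hierarchy score
(standing in for the principal resting-state gradient), the intrinsic
neural timescale, and a myelin-content proxy. The package's pipeline
produces, for a cohort of subjects:

1. an **activation magnitude map** (mean over conditions of the
   across-subject |t| of GLM coefficients),
2. a **task-state FC change map** (ΔGBC = weighted degree of task FC minus
   weighted degree of interval-matched rest FC; negative = reduced
   connectivity during task),
3. the same two maps from the **block-peak approach**, which involves no
   task regression of any kind,
4. a **timescale map** τ from exponential fits to resting autocorrelation
   functions,
5. an **activity flow MAE map** measuring how poorly each region's
   activation is explained by the FC-weighted activations of all other
   regions,

plus an association table (all map pairs, Spearman ρ with
surrogate-map permutation p and bootstrap CI) and paired
transmodal-vs-unimodal contrasts.

# Models and procedures

## Nuisance model

Each run is trimmed by 5 frames, demeaned, linearly detrended, and
residualized on 64 regressors: the 6 motion parameters, their backward
differences (first element 0), and the squares of those 12 (24 motion
regressors); plus 5 principal components each from white-matter and
ventricle compartment signals (aCompCor), their differences, and the
squares of those 20 (40 physiological regressors). "Quadratics of all
regressors" is read as elementwise squares of the expanded set — the only
reading consistent with the counts 6+6+12 = 24 and 10+10+20 = 40. The mean
across parcels is never a regressor: no global-signal regression. Detrending
is linear only; the differencing scheme is backward with a zero first
element (neither is dictated by the source procedures, so both are fixed
here once).

## Activation GLM and FIR task regression

Activations come from ordinary least squares of each parcel on an intercept
plus one regressor per condition: the TR-resolution boxcar (onsets floored
to the TR grid, offsets ceiled) convolved with the canonical double-gamma
HRF (peak delay 6 s, undershoot delay 16 s, unit dispersions,
peak:undershoot 6, kernel scaled to peak 1 over 32 s). No prewhitening or
autocorrelation correction is applied to the GLM errors; group t statistics
across subjects absorb within-subject dependence at the random-effects
level.

For FC, the mean evoked response is removed with an FIR model instead: for
each condition, one indicator column per peri-onset TR from block onset
through offset + 25 TRs, pooled across that condition's blocks. Unlike the
canonical GLM this removes the evoked mean *exactly, whatever its shape* —
the residual block-triggered average is zero to numerical precision — which
is the property that matters when the residuals are about to be correlated.
On dense periodic designs FIR columns of different conditions can be
mutually aliased; aliased columns are dropped with a warning, which leaves
the projection (and therefore the residuals) unchanged.

## Task and rest FC with matched intervals

Task FC is the Pearson correlation over the concatenated in-block samples
of the FIR residuals. Rest FC applies the *identical* computation to
resting data — same FIR design regressed out, same block intervals — so
that task and rest estimates share temporal sampling exactly; under a
stationary null their weighted-degree difference is centred on zero (this
is verified by simulation in the tests). ΔGBC is defined as task − rest
everywhere. Degrees are averaged without Fisher transformation, and a
positive-only variant (negative FC zeroed before averaging) is available
behind a flag.

## The block-peak approach

The alternative route never regresses anything: the preprocessed task run
is baselined to the mean over all inter-block rest TRs, and each block
contributes the element of maximal absolute value (sign kept; ties broken
by earliest TR). Peak averages give activation; block-to-block peak
correlations give FC; pseudo-blocks carved out of rest data by the same
design give the matched rest FC. Keeping the sign preserves deactivations
and keeps the block-to-block correlation well defined; a magnitude-only
mode exists behind a flag. The baseline excludes a configurable post-block
washout (default 0 TRs).

## Intrinsic timescale

Per parcel, the sample autocorrelation (biased estimator, single global
mean) is computed to lag 100 (72 s at TR = 0.72 s; 40 and 50 give
rank-consistent maps) and fit with `R(kΔ) = A[exp(−kΔ/τ) + B]` by
Levenberg–Marquardt least squares under bounds A ≥ 0, τ ≥ 0, B free.
Numerical choices:

* **Lag 0 is excluded** from the fit. It equals 1 by construction, so
  including it over-weights the constraint A(1 + B) = 1 instead of letting
  the decay determine τ.
* **Multi-start**: τ ∈ {0.5, 2, 10} s, A = r(1), B initialized from the
  ACF tail; lowest residual sum of squares wins.
* **Identifiability cutoff**: fits with τ̂ > 5× the observed lag window are
  flagged non-converged — beyond the window the exponential is
  indistinguishable from a line, so such estimates carry no information.
  Non-converged parcels are excluded from group maps rather than clipped.

Group τ maps are across-subject means of per-subject fits (fitting the
group-mean ACF is not used; per-subject fitting matches how per-subject
uncertainty is reported downstream).

## Activity flow mapping

Connectivity weights to each target are the OLS coefficients of the
target's resting series on all other parcels plus an intercept. The full
weight matrix is read off the inverse sample covariance
(β\_{jk} = −Θ\_{jk}/Θ\_{jj}), which is algebraically identical to fitting
each target separately and far faster at hundreds of parcels; the identity
is verified against per-target OLS in the tests. Predictions use no
intercept (the stored β₀ is not part of the propagation rule), and the zero
weight-matrix diagonal makes the leave-target-out property structural.
MAE is the per-region mean of |prediction − actual| over conditions,
averaged across subjects. When a caller supplies fewer timepoints than
parcels, plain OLS is impossible; an explicitly flagged ridge fallback
(penalty by generalized cross-validation) exists for that degenerate regime
but is never used in the reference analyses.

## Surrogate-map statistics

Map correlations cannot be tested by permuting parcels: smooth maps make
parcels exchangeable in value but not in space, and the naive permutation
null is far too narrow (its empirical type-I error on smooth independent
map pairs is ≈ 0.16 at nominal 0.05 in the acceptance run). The package
therefore generates variogram-matched surrogate maps: permute the map's
values, smooth by distance-weighted averaging over each parcel's k nearest
neighbours, realize the affine variogram fit
γ\_target ≈ a·γ\_smooth + b (a, b ≥ 0) as
√a·smoothed + √b·white-noise — the noise term supplies the short-range
"nugget" variance that smoothing alone cannot — and finally rank-remap onto
the source values, so every surrogate contains exactly the source value
multiset in a spatially plausible arrangement. Two design choices matter:

* k is chosen per surrogate from a small grid (3–60 % of parcels) by
  variogram discrepancy;
* the variogram is matched only up to the **25th percentile of pairwise
  distances**. Short-range structure governs a map's effective smoothness;
  matching the full range lets the many long-distance bins dominate the
  objective and leaves the test mildly anticonservative (≈ 0.085 empirical
  α in our calibration experiments, versus ≈ 0.05 with truncation).

The test statistic is Spearman's ρ (Pearson available); p-values are
two-tailed with the add-one correction, so the smallest attainable p is
1/(n_surr + 1). Bootstrap CIs resample parcels with replacement
(percentile). Partition contrasts are paired across subjects: per subject,
the transmodal mean minus the unimodal mean, then a one-sample t
(df = n − 1, with t ≡ 0 for the degenerate all-zero case). FDR control is
Benjamini–Hochberg at q = 0.01 by default.

# The synthetic cohort: what it emulates and why these defaults

The generator is the package's study population; its defaults were chosen
once, on realism grounds, and define the conditions under which the
pipeline's guarantees are demonstrated.

**Geometry and maps.** Parcels are uniform points on a unit sphere with
great-circle distances (default 360 parcels; all code accepts any count
≥ 3). Every planted map is a Gaussian field with exponential spatial
covariance, correlation length 0.15 rad — roughly 15 mm on a 100 mm
hemisphere, smooth enough that naive permutation visibly fails while cross-
map rank correlations stay within ±0.1 of their targets at 180+ parcels.
Cross-map structure is planted through a shared hierarchy latent; target
Spearman correlations (hierarchy–τ +0.6, hierarchy–myelin −0.6,
hierarchy–amplitude −0.6) are converted to latent Pearson values via the
bivariate-normal relation and realized through monotone transforms, so a
noise level of 0 gives exact ±1 rank correlations. τ spans 0.5–5 s; the
myelin proxy spans 1–2 in T1w/T2w-like units.

**Dynamics.** Each parcel is a discrete Ornstein–Uhlenbeck (AR(1)) process
with φ\_i = exp(−TR/τ\_i) and unit stationary variance by construction —
innovations are scaled by √(1−φ²), so no empirical rescaling is needed and
the lag-k autocorrelation is exactly exp(−kΔ/τ\_i), making Eq.-style
timescale recovery a clean oracle. Background coupling enters through 5
shared white-noise drivers with smooth non-negative loadings; the default
coupling strength 0.65 yields mean resting FC ≈ 0.33, in the range of real
parcellated resting data. Because the drivers are white, coupling does not
distort per-parcel autocorrelation.

**Task.** The default design is 24 conditions × 3 blocks of 18 s with
10.8 s inter-block rest at TR = 0.72 s (≈ 2 900 TRs — comfortably more than
the ≈ 1 200 FIR columns). Blocks of 18 s matter: the hemodynamic response
peaks 5–6 s after onset, so much shorter blocks would put the evoked peak
*after* block offset, where the peak approach's inter-block baseline—not
its block window—would absorb it. Evoked responses are
amplitude × HRF-convolved boxcar; the maximum mean amplitude 0.2 yields
evoked peaks of ≈ 1.5–2 noise standard deviations, a realistic
block-design effect size (an order of magnitude stronger would let
condition-to-condition amplitude differences act as a shared block-to-block
gain and contaminate peak FC with mean-evoked signal). Each parcel's
condition profile is a shared modulation (uniform 0.8–1.2) plus a
parcel-specific idiosyncratic component (relative SD 0.5) that no
connectivity-weighted sum of other parcels can predict — this is the
planted "local processing" that activity flow MAE detects; rows are
normalized so each parcel's mean |amplitude| equals its base amplitude
exactly. During task, each parcel's driver coupling is multiplied by
`1 − 0.8 · rank(drive)` where the drive blends activation rank and inverse
timescale rank equally — strongly activating, fast-timescale parcels
suppress their background coupling most, which is precisely the dual
phenomenology the pipeline is built to detect. Confound sets (6 smooth
motion traces, 8 + 8 compartment signals with 3 latent components each) are
mixed into the simulated runs so the nuisance stage has real artifact to
remove.

**What the generator does not emulate.** No voxel/surface structure, no
physiological noise spectra (cardiac/respiratory peaks), no
motion-artifact spatial structure, no hemodynamic variability across
regions (simulation and analysis share the canonical HRF by default — a
deliberately well-specified case; a mismatched-HRF stress mode exists via
the `hrf` argument of `simulate_task_timeseries()`), and no inter-subject
variation in the planted maps. Passing tests therefore demonstrate that the
*estimators and their plumbing* are correct and that the planted effect
structure is recoverable at realistic effect sizes — not that real cortex
satisfies the generative assumptions.

# Degenerate inputs and conventions

* Zero-variance parcels: correlation defined as 0, parcel flagged; an
  all-zero coefficient set gives t ≡ 0 (0/0 convention); zero variance with
  nonzero mean gives an infinite t and a flagged parcel.
* Peak ties: earliest TR wins.
* Rank-deficient FIR designs: aliased columns dropped with a warning
  (projection unchanged). Rank-deficient activation GLMs: error naming the
  aliased columns.
* ΔFC sign: task − rest, everywhere. The alternative reading (rest − task)
  merely negates every FC-change result; the convention here keeps
  "reduction during task" negative.
* Constant maps: surrogates are constant; correlation tests refuse constant
  inputs.

# Problem sizes used in the shipped checks

The reference cohort is 20 subjects × 360 parcels × 24 conditions
(≈ 2 900 task TRs, ≈ 2 900 rest TRs per subject). The packaged tests
demonstrate timescale recovery on AR(1) series of 4 800 samples across
φ ∈ {0.3, 0.5, 0.7, 0.9}; the stationary FC-change null on 100 simulated
subjects at 40 parcels; permutation-test calibration on 500 independent
smooth-map pairs at 100 parcels with 200 surrogates each; and the full
end-to-end cohort at the reference scale with 100 surrogates per
association test. These sizes were chosen so that each check's Monte-Carlo
error is small relative to the effect it verifies while the whole suite
remains convenient to run routinely.

# Known limitations

* The surrogate algorithm is validated by its variogram-matching and
  type-I calibration properties, not by bit-compatibility with any external
  toolbox.
* The timescale fit assumes a single dominant exponential; multi-timescale
  or oscillatory autocorrelation shapes will load on the offset B or fail
  the identifiability cutoff.
* The block-peak FC estimator is an extreme-value statistic: on short
  blocks its rest-side attenuation depends on each parcel's smoothness, so
  peak-approach FC changes carry a τ-dependent bias that only strong
  planted effects (or many blocks) dominate — one reason the reference
  design uses 72 blocks.
* Group-level association tests operate on group-mean maps; per-subject
  association variants are not part of the pipeline output.
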