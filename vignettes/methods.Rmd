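---
title: "Methods: accordance connectomics and dose-response PLSC for pre/post resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accordance connectomics and dose-response PLSC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

neofc implements a connectome-based analysis of *stimulus-induced
modulation of resting-state functional connectivity* (RS-FC), designed
around a neonatal study layout: three groups of newborns (a music-exposed
preterm group PM, a preterm control group PC, and a full-term control
group FT), each scanned in two resting-state runs separated by a musical
stimulus, with around 15 subjects per group, 300 volumes per run at TR
1.6 s, and a 90-region atlas parcellation. The scientific questions the
pipeline answers are:

1. *Per group*: which region pairs show higher coupling after the
   stimulus than before (run 2 > run 1)?
2. *Between the preterm groups*: which of those increases are specific to
   prior music exposure, over and above the effect of hearing the music
   once in the scanner?
3. *Within the exposed group*: does the amount of prior exposure (the
   "dose": number of intervention sessions, 7-35) correlate with the
   per-region connectivity change?

Real infant imaging data of this kind are generally not shareable, so the
package ships a synthetic cohort generator with the same structure and
known planted effects; every statistical stage is validated by
calibration and parameter-recovery studies on such cohorts.

## Volume censoring

Motion-corrupted volumes are removed before any statistic is computed.
A volume triggers censoring when its framewise displacement (FD, Power
convention: sum of absolute backward differences of the six rigid-body
parameters, rotations converted to arc length on a 50 mm sphere) exceeds
0.5 mm, or when DVARS (spatial standard deviation of the volume-to-volume
difference, as a percent of the run-mean within-mask intensity) exceeds
3%. The trigger is removed together with the one preceding and two
following volumes; windows are clipped at run boundaries and unioned
across triggers. A run enters the analysis only when at least 50% of its
volumes survive, with the boundary counted as retained (`>= 0.5`).

Two conventions are worth making explicit because the thresholds do not
define them:

* the DVARS percent baseline is the run-mean within-mask intensity, which
  makes the measure invariant to global intensity scaling;
* censored volumes are *dropped* and the retained series concatenated; no
  interpolation is attempted, and the band-pass filter runs on the
  concatenated series. This is a deliberate simplification, and its
  main cost — spectral leakage across concatenation seams — is shared by
  every stage equally and is absorbed into the calibration studies.

Censoring is idempotent: a censored trace contains no remaining triggers,
so re-censoring changes nothing. The implementation is pinned against a
brute-force window-union oracle in the tests.

## Grey-matter masking and signal cleaning

When starting from voxel data, a voxel keeps its atlas label only when
P(GM) is at least as large as both P(WM) and P(CSF); ties retain the
voxel, because removal is triggered by a strict inequality. Regional
series are the means over each label's retained voxels; a region left
with no voxels is set to missing and flagged.

Nuisance regression and detrending are performed *jointly*: each regional
(or voxel) series is residualized by ordinary least squares against a
single design of intercept, linear trend, and any supplied nuisance
regressors (CSF, WM, motion), after the censored volumes have been
dropped. A joint design avoids the order ambiguity of sequential
residualization. The default motion regressors are the six rigid-body
parameters themselves (not their derivatives).

## Band-pass filter

The canonical resting-state band 0.01-0.1 Hz is isolated with an order-4
Butterworth filter applied forward and backward (zero phase, effective
order 8). Two numerical choices matter at the 300-volume scale:

* each series is demeaned before filtering, and
* the series is extended by odd reflection over roughly one low-cutoff
  period (1/0.01 Hz worth of samples) per side before `filtfilt`, then
  trimmed. Without this padding, start-up transients of the low cutoff
  (time constant about 100 s, i.e. ~60 samples at TR 1.6 s) leak visibly
  into the output.

The tests verify ~unit gain at 0.05 Hz, >10-fold attenuation at 0.2 Hz,
and near-cancellation of constants.

## The accordance connectome

Coupling between regions is measured by *accordance*, a connectivity
measure built from threshold crossings rather than from products of
amplitudes, which makes it robust to heavy-tailed BOLD noise. For region
i with series x_i, define the upper- and lower-excursion indicators

    u_i(t) = 1 if x_i(t) > q_high quantile of x_i,  else 0
    d_i(t) = 1 if x_i(t) < q_low  quantile of x_i,  else 0

and the concatenated indicator e_i = [u_i; d_i]. Then

    accordance(i, j)  = (u_i . u_j + d_i . d_j) / (||e_i|| ||e_j||)
    discordance(i, j) = (u_i . d_j + d_i . u_j) / (||e_i|| ||e_j||)

Identical series score accordance 1; sign-flipped series score accordance
0 and discordance 1; by Cauchy-Schwarz, accordance + discordance <= 1
pairwise. Because the thresholds are within-region quantiles computed on
the retained volumes, the measure is invariant under strictly increasing
affine transforms of any single region's series.

The default quantiles 0.158/0.842 correspond to +/-1 SD tails of a
normal; the literature on excursion-based coupling commonly thresholds
around one standard deviation, and the exact choice is exposed as
configuration (`q_low`, `q_high`). All downstream statistics consume the
upper triangle of the symmetric matrix; the unit diagonal is excluded.

Nodal strength is the weighted degree (row sum minus diagonal); *delta
nodal strength* is the run-2 minus run-1 strength per region, the
per-subject imaging feature of the PLSC stage.

## Per-group edge statistics and the fused contrast

For every one of the 4005 edges, a paired t-test of the run-2 minus run-1
differences across a group's subjects, one-sided for an increase, with
Cohen's d for the paired design defined as mean(diff)/sd(diff) using the
unbiased standard deviation (other d variants for paired designs divide
by a pooled or average SD; the differences-SD convention is stated here
once and used everywhere). No multiplicity correction is applied — with
n = 15 per group the design is exploratory, and the package instead uses
a strict reporting threshold (p < .001 by default, configurable). Edges
whose differences have exactly zero variance are flagged degenerate and
excluded rather than assigned an arbitrary p, so the downstream z-fusion
stays well defined.

The exposure-specific contrast converts each group's one-sided p-values
to z-scores through the standard-normal quantile, z = qnorm(1 - p), and
fuses the two preterm groups as

    z_diff = (z_PM - z_PC) / sqrt(2)

Under the joint null with independent groups, var(z_PM - z_PC) = 2 by the
variance sum law, so z_diff is standard normal and is thresholded
directly; the default threshold 2.58 is the upper 0.005 quantile. The
tests confirm both the analytic variance and, on a fully null synthetic
cohort, that the empirical z_diff distribution passes a
Kolmogorov-Smirnov test against N(0, 1) and that the p < .001 edge count
falls in its binomial window.

## Dose-response PLSC

Partial least squares correlation relates the PM subjects' delta nodal
strength (X, subjects x 90) to their exposure dose (Y, subjects x 1).
Both blocks are z-scored across subjects; the cross-covariance
R = Y'X/(n-1) is decomposed as R = U S V'. With a single outcome there is
exactly one component and a useful closed form: **V is the
unit-normalized vector of dose/region correlations and S is that vector's
norm**. This closed form is the central correctness anchor of the module
(oracle equivalence to 1e-10 in the tests). Latent scores are Lx = XV,
Ly = YU.

*Sign convention.* The SVD sign is arbitrary. The package orients the
single-outcome component so the outcome salience U is positive, which
makes every brain salience read directly as the sign of that region's
dose correlation — the interpretation the salience plots rely on. (An
alternative convention, making the largest-|V| element positive, leaves
the orientation relative to the dose arbitrary: whenever the strongest
region happens to be negatively dose-coupled the whole pattern flips,
which scrambles sign-recovery summaries. With more than one outcome,
where no outcome direction is privileged, the largest-|V| rule is used.)

*Permutation test* (default 5000 draws): outcome rows are permuted
against imaging rows, the null statistic is the singular value, and
p = (1 + #{S_perm >= S_obs}) / (1 + n_perm); the add-one convention keeps
p positive. With one outcome the permuted singular values are batch
vector norms, so even 5000 permutations are effectively instant.

*Bootstrap stability* (default 200 samples): subjects are resampled with
replacement, each refit restandardized and sign-aligned to the reference
fit, and each region summarized by its bootstrap mean and 5th/95th
percentiles; a salience is *robust* when that interval excludes zero. A
bootstrap-ratio rule (|mean/SD| >= 2.58) is available as
`method = "ratio"`. Degenerate resamples (zero-variance column) are
redrawn and counted.

*LOOCV*: each fold learns the standardization and the saliences on n - 1
subjects and projects the held-out subject with the *training*
parameters; the Pearson correlations between full-model and
cross-validated latent scores summarize robustness to left-out samples.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions: groups FT/PC/PM of 16/15/15, two runs of 300 volumes at TR
1.6 s, 90 regions, and doses drawn from round(N(25, 8.92)) clamped to
[7, 35].

* *Signal model*: stationary zero-mean Gaussian AR(1) (lag coefficient
  0.3 by default) with a block-structured cross-sectional covariance
  (blocks of 10 regions at within-block correlation 0.3) standing in for
  resting-state community structure. Run 2 uses the same process with
  each planted edge's covariance increased by its `delta`; a planting
  that breaks positive definiteness is rejected with a diagnostic.
* *Dose effect*: for each PM subject, the increments on the dose-effect
  nodes are scaled by u = r z_dose + sqrt(1 - r^2) eta with eta standard
  normal, positively for the positive node set and negatively for the
  negative set, so the generating correlation between the planted nodal
  delta and the dose equals r in law (default 0.8).
* *Motion*: spikes occur independently per volume (default rate
  0.02/volume, which with the 4-volume scrub window censors roughly
  25-30 of 300 volumes, in line with published neonatal exclusion
  counts); a spike adds a global intensity jump to the signals and an
  FD and DVARS exceedance at the same volume, so the two censoring
  criteria can be exercised jointly and separately.

What the generator does *not* emulate: hemodynamic response shapes,
physiological (cardiac/respiratory) noise structure, scanner drifts
beyond a linear trend, spatial voxel-level structure, and distance-
dependent motion artifacts. Passing calibration and recovery tests on
these cohorts therefore demonstrates the statistical machinery is
correct and calibrated for Gaussian AR(1-ish) inputs — not that effect
sizes on real infant data would match.

*Detectable effect sizes* (calibrated empirically, fixed once): a planted
covariance increment of 0.4-0.6 on unit-variance regions is reliably
recovered by the edge statistics at n = 15-16; nodal-delta recovery
through the full accordance stage needs increments near 0.6 at 300
volumes. Design-level PLSC studies plant the dose correlation directly
(r = 0.9 for power/recovery studies).

## Problem sizes used by the test and acceptance suites

The suites run null-cohort calibration at the full study scale (15 + 15
subjects, 90 regions, 300 volumes), PLSC calibration with 200 replicates
of n = 15 x 90 designs at 500 permutations and 200 bootstrap samples per
replicate, and oracle equivalence on 1000 random censoring traces and
10-region accordance inputs; the end-to-end determinism check runs the
full default pipeline twice. These sizes were chosen so the whole suite
completes in a couple of minutes while every binomial acceptance window
still has useful width.

## Known limitations

* *Percentile-bootstrap false flags at n = 15.* The 5th-95th percentile
  rule marks a pure-noise region "robust" in roughly 15% of cases at
  n = 15 (the acceptance study measures ~84-85% specificity with either
  200 or 1000 bootstrap draws). This is inherent to percentile intervals
  for correlation-type statistics at small n — the bootstrap distribution
  centers on the sample estimate, which is itself dispersed — and is why
  the more conservative bootstrap-ratio rule is provided as an
  alternative. Robust-salience tables at this sample size should be read
  as descriptive stability summaries, not calibrated hypothesis tests.
* *End-to-end dose-effect power.* Delta nodal strength sums 89 accordance
  edges, each carrying estimation noise at 300 volumes; the resulting
  per-region noise dwarfs any covariance-level dose modulation that still
  keeps the planted run-2 covariance positive definite, so the PLSC stage
  does not reach significance on end-to-end synthetic cohorts at n = 15.
  The PLSC calibration and recovery studies therefore plant the dose
  correlation at the design level, which exercises the inference
  machinery at controlled effect sizes.
* Band-pass on concatenated censored series ignores the true temporal
  gaps at the seams.
* The t-test's p < .001 tail calibration on accordance differences relies
  on approximate normality of edge differences at n = 15; the null-cohort
  study confirms it holds for the generator's signal model, not for
  arbitrary real-data noise.
* The 90-entry region lookup follows the standard automated anatomical
  labelling order; atlases with different label orders need a substitute
  lookup.
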