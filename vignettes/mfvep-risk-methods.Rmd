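---
title: "Multifocal VEP features and conversion risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifocal VEP features and conversion risk: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiologically isolated syndrome (RIS) describes people whose brain MRI
shows demyelinating-looking lesions without any clinical episode.  A
fraction of them later convert to clinically isolated syndrome or multiple
sclerosis, and anticipating who will convert matters for monitoring and
treatment decisions.  Multifocal visual-evoked potentials (mfVEPs) probe
the visual pathway at 60 visual-field sectors simultaneously and are
sensitive to subclinical demyelination (latency) and axonal loss
(amplitude).

This package implements an mfVEP feature-extraction and classification
pipeline for that question: windowed signal-to-noise ratio (SNR) with
best-channel selection, cross-correlation latency against a normative
database, two continuous-wavelet-transform (CWT) scalogram descriptors,
per-patient aggregation, group statistics with ROC and Kaplan-Meier
analysis, and a RUSBoost classifier cross-validated leave-one-out.  The
clinical recordings behind the published study are not openly deposited,
so the package also contains a calibrated synthetic cohort generator; every
stage is exercised, tested and benchmarked on synthetic data whose group
structure is calibrated to the published group means.

## Recording geometry and preprocessing

One eye's recording is a 60 sectors x 6 channels x 600 samples array at
1200 Hz (500 ms records).  Channels 1-3 are recorded bipolar derivations;
channels 4-6 are their pairwise differences A-B, B-C, A-C
(`derive_channels()`), the standard multichannel-mfVEP construction — the
recording protocol mentions three derived channels without printing the
formula, and pairwise differences are the conventional choice.

Records are digitally band-passed 1-35 Hz with a zero-phase brick-wall FFT
filter (`bandpass_fft()`): frequency bins outside the band are zeroed and
the record inverse-transformed.  A brick-wall filter is used, rather than
an FIR/IIR design, because the protocol names the FFT explicitly; its
ringing is immaterial on band-limited synthetic data.  The filter is
idempotent and exactly energy-preserving in band, which the tests assert.

Two analysis windows partition each record: the signal window 45-150 ms
(evoked response) and the noise window 325-430 ms (noise floor).  Windows
are half-open `[lo, hi)` in ms, mapped to 0-based samples by
`round(t * fs / 1000)`; at 1200 Hz both windows then hold exactly 126
samples, which keeps RMS comparisons between them balanced.  The source
protocol does not state inclusivity; this convention is fixed here.

## Time-domain features

The SNR of one sector/channel is the RMS amplitude of its signal window
divided by the mean noise-window RMS over all 60 sectors.  The denominator
is computed per channel (60 noise RMS values of that channel within the
eye), the standard construction in which each derivation has its own noise
floor; a pooled all-channel denominator is available via the `scope`
argument.  Per sector only the best channel — the one with the highest
SNR, ties to the lowest channel index — is analysed, and the eye-level SNR
is the mean best-channel SNR over the 60 sectors.

Monocular latency is the lag maximising the normalised (Pearson)
cross-correlation between a sector's best-channel waveform and the
corresponding normative-database template, searched over integer-sample
lags within ±50 ms; positive lags mean the subject is delayed.  Latency is
therefore *relative to the normative database* (near-zero values for
normal timing), which is the only reading consistent with the published
sub-millisecond group means.  The correlation uses the full 600-sample
filtered record: the 105 ms signal window alone is too short to support
±50 ms lags.  Normalised rather than raw correlation ensures amplitude
differences do not bias the latency.  Ties are broken by the smallest
absolute lag, then negative before positive.  Because the study's
normative database is unpublished, the package synthesises one (mean
best-channel waveform over simulated healthy eyes); absolute latencies are
therefore only comparable within the synthetic cohort.

## Wavelet-domain features

The CWT used is `T(a, b) = 1/sqrt(a) * integral x(t) psi((t - b)/a) dt`
with the real Daubechies-7 wavelet.  No installed R package tabulates db7
for a continuous transform, so the package reconstructs the wavelet
function from the standard 14-tap filter bank by the cascade algorithm
(`level = 10`, grid step 2^-10 over the support [0, 13]); a handful of
tabulated values are frozen in the tests against an independently computed
reference.  The transform itself is a discrete cross-correlation of the
zero-padded waveform with the sampled dilated wavelet, FFT-accelerated in
compiled code, with an R double-loop reference implementation
(`method = "direct"`) that the tests hold to 1e-9 agreement.

Two conventions are deliberately fixed and documented because the source
does not state them:

* **Translation alignment.** The translation axis is aligned to the centre
  of the dilated wavelet support (the convention of the legacy Matlab
  `cwt`), so `b` reads as the time at which the wavelet is centred on the
  record's own time base.  Aligning to the support's left edge instead
  would place the published group b_max values (139-169 ms) outside any
  plausible response timing.
* **Scale grid.** 48 logarithmically spaced, integer-rounded dilations
  over [8, 128] samples (44 distinct after rounding), spanning db7
  pseudo-frequencies of about 6.5-103 Hz at 1200 Hz.  This covers the
  evoked response's energy band while keeping the dilated support
  (about 13a samples) commensurate with the 600-sample record.  Absolute
  N_max counts are grid-dependent; only contrasts between groups are
  meaningful, and all preset calibrations are defined with respect to this
  default grid.

From the modulus surface `|T(a, b)|` of each sector's best channel two
descriptors are taken: **b_max**, the translation (ms) of the global
modulus maximum (ties: smallest translation, then smallest scale), searched
over the full 0-500 ms record because the published means exceed the
150 ms window edge; and **N_max**, the number of strict 8-neighbourhood
local maxima exceeding one third of the global maximum (strict inequality;
equal-valued plateaus are merged by connected components and rejected when
they leak into non-maximal cells).  Eye-level values are the means over
the 60 sectors; sectors with an identically zero modulus are excluded with
a warning.

Numerical detail of the FFT backend: each scale uses the smallest
5-smooth transform length `L >= n + max(C, K - C)` (kernel length K,
centre C).  Only the n centre-aligned lags are ever read back, so every
circular alias of a read lag falls outside the kernel-signal overlap even
though L is about half the full linear-correlation length at coarse
scales; kernels longer than L are folded modulo L.  The direct-summation
engine validates this exactly.

## Per-patient aggregation

Each patient contributes the *worse eye* in each sense: `SNR_min` (the eye
with the lesser amplitude, quantified as the smaller eye SNR), `Lat_max`
(the eye with the greatest delay, signed lag), and the larger of the two
per-eye means for `b_max` and `N_max`.  Signed rather than absolute lag is
used for `Lat_max`; the published near-zero group means admit either
reading.  Patients with a single usable eye are an error by default and
can be admitted explicitly (flagged) — the study cohort had none, and they
are excluded from group statistics.

## The synthetic cohort generator

The generator is the package's stand-in for the unavailable recordings,
and its defaults *are* the study conditions: 60 x 6 x 600 records at
1200 Hz, a 5 converter / 10 non-converter cohort (the study's 1:2
imbalance), and conversion times 9, 10, 11, 12 and 18 months with
censoring at 24 — four conversions within the first year and a fifth in
the second, matching the published survival figures and the 9-19 month
range of observed conversions.

**Evoked model.** Each sector's three recorded channels carry the same
evoked waveform (scaled by a sector gain and the group amplitude, shifted
by a continuous per-sector latency jitter) plus independent white noise,
then band-passed 1-35 Hz.  The evoked waveform is a *main biphasic
complex* (first derivative of a Gaussian, width 10 ms) centred at
`peak_time` inside the signal window, plus a *late complex* (relative
amplitude 1.4, width ratio 1.5) delayed by 45 ms times the group's
dispersion factor.  The late slow complex is what real mfVEP responses
carry after the primary deflection, and it is essential here: it holds the
dominant coarse-scale scalogram energy, placing b_max tens of ms after the
main peak — a single biphasic bump cannot reproduce the published b_max
means (139-169 ms, beyond the window edge) from a peak inside the signal
window, because its scalogram maximum sits slightly *before* its peak at
every scale.  Dispersion (the demyelination surrogate) widens both
complexes and delays the late one, raising b_max; amplitude loss (the
axonal-loss surrogate) lowers SNR.  The converter dispersion factor
(1.8) was chosen in a clean-template design scan so that, after
calibration, converter and non-converter peak times nearly coincide —
keeping the latency contrast small, as in the published comparison where
Lat_max did not separate the groups.

Latency jitter is applied by re-evaluating the analytic waveform at the
jittered peak rather than by integer-sample shifting: sub-sample jitter
smooths the otherwise grid-quantised per-sector b_max distribution, which
matters for calibration (below).  Sector gains default to a mild
eccentricity falloff over the five dartboard rings (1, 1, 0.9, 0.8, 0.7,
twelve sectors each); the stimulus is eccentricity-scaled but no values
are printed, so this profile is a documented choice.  Per-sector
amplitude/latency distributions beyond the group means are likewise not
published; the generator's higher moments (noise SD 1, jitter SD 2 ms) are
realistic choices, documented as such, and calibration targets group means
only.  Two eyes of a patient are independent noise realisations of the
same preset — the simplest model consistent with min/max aggregation
across eyes.  No check-reversal, m-sequence, inter-eye correlation or
ocular-artifact structure is modelled.

**Calibration.** Group presets are calibrated so that the
*pipeline-extracted* means match the published group means (eye SNR 4.07
non-converter / 2.74 converter; eye b_max 139.03 / 169.44 ms).  Each
target gets an analytic placement followed by empirical correction on
seeded batches:

* *Amplitude*: the closed form `A = sigma * sqrt(SNR^2 - 1)` (the
  first-order inversion of the SNR expectation for a unit-RMS template in
  equal-variance noise) evaluated at the post-filter effective noise SD,
  followed by one rescale
  `A1 = A0 * sqrt((target^2 - b0^2) / (m0^2 - b0^2))` using a measured
  noise-only eye SNR `b0` (best-channel selection bias, about 1.3) and a
  measured mean `m0` at `A0`.  The rescale batch runs at the *final*
  timing because the extracted eye SNR depends weakly on the peak time
  through window-edge effects.
* *Timing*: the peak is first placed so that the noise-free waveform's
  b_max on the default scale grid equals the target; noise then biases
  the extracted mean (competing scalogram structure wins in a fraction of
  sectors), and the bias drifts slowly with peak time, so a unit-slope
  shift towards the target is iterated three times — two half-size
  batches, then a full one; the mean responds to the peak time with a
  slope close to one, so each pass cuts the remaining bias by an order of
  magnitude and the final batch's sampling noise sets the limit.

Default batch sizes (800 eyes for the SNR rescale, 200 noise-only,
300 + 300 + 600 for the timing shifts) put the calibration standard error well
below the evaluation standard error of the 200-eye recovery checks in the
acceptance suite.  Calibration is deterministic given its seed and takes
a few minutes of CPU; it is recomputed from scratch wherever it is needed
rather than shipped as constants.

**What passing tests do and do not show.**  The synthetic cohort
reproduces the *statistical structure* the analysis assumes — group mean
contrasts, imbalance, band-limited noise, event timing — not real mfVEP
morphology, artifacts, inter-sector correlation, or the study's normative
database.  Recovery of calibrated means and directional replication at
cohort scale validate the pipeline's implementation, not the clinical
effect sizes; absolute N_max and latency values in particular are
generator- and grid-specific.

## Statistics

Group comparisons use the pooled-variance Student t test for `SNR_min`,
`Lat_max` and `b_max` and the Mann-Whitney rank-sum test for `N_max`,
two-tailed, as in the published table (Welch is available by flag).  The
rank-sum p is exact — full enumeration over group assignments with
midranks — up to combined n = 20, beyond which a tie-corrected normal
approximation (no continuity correction) is used.  The Fisher exact test
(for categorical cohort descriptors) sums hypergeometric probabilities no
larger than the observed table's.  No multiple-testing correction is
applied, matching the published raw p-values; Holm adjustment is one
argument away.

Per-feature discrimination is the empirical AUC with half credit for
ties.  Directions are fixed and documented: converters score higher on
`b_max`, `N_max` and `Lat_max`, lower on `SNR_min` (negative-up), which is
what makes the published AUC of 0.92 for a variable *lower* in converters
coherent.  Survival uses the Kaplan-Meier product-limit estimator
(`survival::survfit`), events before censorings at tied times.

## Classification

RUSBoost (random-undersampling boosting) addresses the 1:2 class
imbalance: each round fits a weak learner on a balanced subsample —
all minority cases plus a uniformly undersampled majority at the
configured ratio, carrying the current boosting weights — while the
AdaBoost.M1 weight update (pseudo-loss `eps`, `beta = eps / (1 - eps)`,
correctly classified weights multiplied by `beta`) runs on the full set.
Rounds with `eps >= 0.5` are rejected and resampled (10 retries, then the
ensemble stops early with a warning); `eps = 0` floors `beta` at 1e-10.
The binary AdaBoost.M1 form is used rather than AdaBoost.M2 since the task
is two-class.  The weak learner is an `rpart` tree of depth 2 with case
weights; 30 rounds and a 1:1 post-sampling ratio are the defaults — the
study names only "RUSBoosted Trees", so depth, rounds and ratio are
declared assumptions, all configurable.

Prediction scores are the normalised weighted vote
`sum alpha_t [h_t(x) = 1] / sum alpha_t` in [0, 1] with
`alpha = log(1/beta)`; labels threshold at 0.5 (ties positive).
Cross-validation with folds equal to n is leave-one-out — the study's
15-fold protocol on 15 patients; otherwise folds are stratified and
seeded.  Out-of-fold scores pool into a single ROC; sensitivity and
specificity are taken at the vote threshold.  Because the published
"perfect" figures do not say whether they are out-of-fold or training-set
values, the report carries both.  On synthetic cohorts perfect metrics
are expected only in the wide-margin regime; the acceptance suite instead
checks directional replication and a label-permutation null centred near
AUC 0.5 (the band allows the known small-sample pessimism of leave-one-out
scoring under the null).

## Problem sizes and budgets

The test and acceptance workloads are sized for a single CPU: 200 eyes
per group for calibration-recovery checks (two standard errors of the
200-eye mean as the band), 100 seeded 15-patient cohorts for directional
replication, 100 label shuffles for the permutation null, and exhaustive
enumeration oracles only up to n = 10 (tests) / 20 (implementation).
These sizes are the package's chosen study conditions for its synthetic
experiments.

## Known limitations

* Latency and N_max behave generator-specifically.  The dispersed
  converter complex correlates with the (non-converter-shaped) normative
  templates at a clearly positive lag, so the synthetic latency contrast
  is much larger than the near-zero published one — plausible for
  demyelination, but not a replication.  And the synthetic converters'
  smoother, more dispersed scalograms carry slightly *fewer* prominent
  local maxima than non-converters', the opposite direction to the
  published N_max contrast; neither variable is calibrated, and neither
  enters the acceptance checks or the classifier inputs.
* The amplifier's analogue band (3-100 Hz) is not modelled on top of the
  digital 1-35 Hz filter.
* The normative database is synthetic; absolute latencies are not
  comparable to clinic values.
* Single-eye patients are supported mechanically but excluded from group
  statistics by default.
* The b_max search spans the whole record, so very low SNR can place
  b_max on noise structure anywhere in 0-500 ms; calibration accounts for
  the resulting mean bias but not for its tails.
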