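# mfvepris

Multifocal visual-evoked potential (mfVEP) features as prognostic markers
of clinical conversion in radiologically isolated syndrome (RIS).

People with RIS have MRI lesions suggestive of demyelinating disease but
no clinical episode; a fraction later convert to clinically isolated
syndrome or multiple sclerosis.  mfVEPs record cortical responses to 60
independent visual-field sectors per eye and are sensitive to subclinical
damage along the visual pathway.  This package implements, end to end,
an mfVEP analysis for the conversion-risk question, together with a
calibrated synthetic cohort generator so the whole pipeline runs and is
tested without access to clinical recordings.

## The features

Each eye is a 60 sectors x 6 channels x 600 samples ensemble at 1200 Hz,
band-passed 1-35 Hz (zero-phase FFT filter).  Per sector, only the best
channel is analysed — the one maximising

    SNR (V/V) = RMS(X[45-150 ms]) / mean(RMS(X[325-430 ms]))

(signal-window RMS over the channel's mean noise-window RMS across all 60
sectors).  From the best channel per sector the pipeline extracts, per
eye: the mean SNR; the mean latency (lag of maximum normalised
cross-correlation against a normative database, ms); and two descriptors
of the db7 continuous-wavelet-transform scalogram |T(a,b)| —

* `b_max` — the translation (ms) at which the absolute scalogram maximum
  appears, and
* `N_max` — the number of scalogram local maxima exceeding one third of
  that maximum,

averaged over the 60 sectors.  Per patient, the worse eye is kept:
`SNR_min`, `Lat_max`, and the larger per-eye mean of `b_max` and `N_max`.
Group analysis uses t / rank-sum tests, per-feature empirical AUC, and
Kaplan-Meier conversion-free survival; classification feeds (`SNR_min`,
`b_max`) to a RUSBoost ensemble of depth-limited trees with leave-one-out
cross-validation, the standard remedy for the cohort's 1:2
converter:non-converter imbalance.

The synthetic generator emulates the study conditions: evoked responses
with their main complex in the 45-150 ms window plus a dispersion-scaled
late complex, 1-35 Hz band-limited noise, a 5/10 converter/non-converter
cohort, and conversion at months 9-12 and 18 with censoring at 24.  Group
presets are calibrated so pipeline-extracted means match the published
group means (SNR 4.07 vs 2.74; b_max 139.03 vs 169.44 ms).  See the
methods vignette (`vignettes/mfvep-risk-methods.Rmd`) for every model
choice and its rationale.

## Worked example

```r
library(mfvepris)

config  <- generator_config()
presets <- calibrate_presets(mfvep_presets(), config, seed = 1)  # ~ minutes
cohort  <- generate_cohort(5, 10, config, presets, seed = 1)
ndb     <- build_normative_db(8, config, presets$healthy, seed = 12)

feats <- cohort_features(cohort, ndb)
compare_groups(feats$patients)[, c("feature", "mean_non_conv",
                                   "mean_conv", "test", "p", "auc")]

km <- km_estimate(cohort$events)
c(S12 = km_surv_at(km, 12), S24 = km_surv_at(km, 24))
#>       S12       S24
#> 0.7333333 0.6666667

rep <- cross_validate(feats$patients[, c("snr_min", "bmax_ms")],
                      as.integer(feats$patients$group == "RIS_conv"),
                      folds = 15, seed = 24)
c(sens = rep$sensitivity, spec = rep$specificity, auc = rep$auc)
```

The survival readout says 73.3% of the 15 patients remain conversion-free
at one year (4 of 15 convert by month 12) and 66.7% at two years (a fifth
conversion at month 18).

The same workflow, split into narrative steps that write their tables
under `results/`, lives in `analysis/01_simulate_cohort.R` through
`analysis/04_classify.R` (run them in order from the repository root).
On its fixed seed the staged run prints:

```
group comparison (non-converters vs converters):
     feature mean_non_conv mean_conv     test        p auc
1    snr_min          3.99      2.71        t 4.00e-16   1
2 lat_max_ms          0.29     30.51        t 1.09e-10   1
3    bmax_ms        139.39    173.26        t 6.88e-16   1
4       nmax         19.28     17.29 wilcoxon 6.66e-04   0
conversion-free survival: 73.3% at 12 months, 66.7% at 24 months
leave-one-out: sensitivity 1.00, specificity 1.00, AUC 1.00
```

Each row gives the group means of one patient-level variable, the
designated test's two-tailed p, and the empirical AUC with the documented
direction (lower `SNR_min`, higher `b_max` in converters).  The calibrated
contrasts in `SNR_min` and `b_max` separate the synthetic groups cleanly
(the classifier is perfect out of fold at this effect size); latency and
`N_max` behave generator-specifically — see the limitations section of the
methods vignette before reading anything into those two rows.

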