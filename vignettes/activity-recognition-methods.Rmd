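---
title: "Methods: smartphone activity recognition for stroke cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone activity recognition for stroke cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeAR)
```

## The problem

Activity-recognition (AR) classifiers for wearable sensors are usually
trained on laboratory recordings of young, healthy adults. After a stroke,
gait slows and becomes more variable, and activities performed at home look
different from the same activities performed under supervision in a lab. Both
shifts degrade a deployed classifier, and the failure mode matters clinically:
a model that mistakes slow, low-amplitude walking for standing underestimates
exactly the ambulation that rehabilitation aims to restore.

`strokeAR` implements the full analysis chain for studying these effects with
a waist-worn smartphone (tri-axial accelerometer and gyroscope at a nominal
60 Hz, barometer at 6 Hz; six self-labeled activities: Sitting, Lying,
Standing, Stairs Up, Stairs Down, Walking), together with a synthetic
multi-sensor recording generator that stands in for human subject data, which
is not publicly available for this study design. Every stage is exposed as an
ordinary R function; the classifier is a standard S3 modelling object.

## Pipeline

1. **Ingestion and resampling** (`read_recording`, `resample_stream`).
   Streams are validated (strictly increasing timestamps, finite values) and
   linearly interpolated onto uniform grids: 50 Hz for the inertial sensors,
   6 Hz for the barometer. The original acquisition method is jittered and
   multi-rate, so resampling is exercised on irregular input. Linear
   interpolation was chosen because it is order-preserving and exact on ramps;
   the original analysis does not specify its interpolation method, so this is
   a documented package decision.

2. **Artifact trimming** (`trim_bout`, `sample_entropy`). Labeling an
   activity involves handling the phone, which injects 1–3 s of broadband
   noise at bout edges. The trimmer scans 1-s subwindows of the accelerometer
   norm inward from each bout end in 0.25-s hops and computes SampEn(m = 2)
   with tolerance r = 0.2 times a robust bout-level scale (the median
   subwindow SD). Clean signal — smooth postural sway or quasi-periodic gait —
   scores well below the thresholds (0.5 stationary, 1.5 ambulatory), while
   broadband handling noise scores far above, so the end is trimmed to the far
   edge of the last above-threshold window, capped at 5 s per end. The
   thresholds, subwindow length and tolerance are decisions, not
   reconstructions: the original work states only that an activity-dependent
   sample-entropy threshold was used. Verified behavior (unit and
   acceptance tests): ≥90% of injected artifact seconds are removed at ≤0.5 s
   mean clean-signal loss, clean bouts are untouched, all-artifact bouts trim
   at the cap, and a second pass trims nothing.

3. **Mislabel filtering** (`drop_mislabeled`). Bouts labeled as an ambulatory
   activity whose accelerometer-norm SD over the bout is below 0.05 m/s²
   (near-flat signal) are removed, mirroring the manual removal of obviously
   mislabeled trials. The rule deliberately touches only ambulatory labels.

4. **Segmentation** (`segment_clips`). Trimmed bouts are cut into 10-s clips
   with 90% overlap (1-s step): a bout of usable duration T yields
   floor(T − 10) + 1 clips, each with exactly 500 samples per inertial axis
   and 60 barometer samples. Clips never span bout boundaries.

5. **Features** (`feature_catalog`, `extract_inertial_features`,
   `extract_barometer_features`, `build_instance_table`). 270 features per
   clip: 131 per inertial sensor (38 per axis: mean, range, IQR; SD, skew,
   kurtosis; four z-score histogram fractions on [−2, 2]; four first-derivative
   moments; four power-spectrum moments; twenty 0.5-Hz band powers over
   0–10 Hz — plus 17 cross-axis features: three Pearson correlations, raw and
   normalized mean cross products and their absolute variants for the three
   axis pairs, the mean squared norm, and the sum of axial SDs) and 8 from the
   barometer (four derivative moments, SD, range, IQR, OLS pressure slope).

6. **Feature ranking** (`rank_features_oob`, `select_features`):
   out-of-bag permutation importance of a random-undersampling bagged forest
   (per-tree class-balanced sampling), importance normalized by its SD across
   trees; top-k selection with k = 151 as the conventional default. The
   surviving set is data-dependent and is not treated as a reproducible
   quantity.

7. **Classifier** (`rusboost`, `rf_baseline`). RUSBoost: AdaBoost.M2 boosting
   of CART trees where each iteration trains on a random undersample that
   equalizes class counts at the minority-class size (drawn with replacement
   only when a class is smaller than the target). Defaults follow the stated
   hyperparameters: 200 trees, learn rate 1, minimum leaf 5. The pseudo-loss
   is evaluated on the full weighted set; boosting stops early at pseudo-loss
   0 (large capped learner weight, ln(1e10)) or ≥0.5. Prediction is the
   argmax of alpha-weighted tree probability votes with deterministic
   alphabetical tie-breaks. A plain bootstrap random forest (no undersampling)
   is the baseline for the imbalance comparison.

8. **Evaluation designs** (`eval_population`, `stratify_by_impairment`,
   `eval_environment`, `learning_curve`, `ablate_barometer`,
   `compare_reports`). Population models use leave-one-subject-out
   cross-validation within a cohort, or train once on the full source cohort
   for cross-cohort designs; per-subject confusion matrices support the paired
   statistics. Impairment stratification re-aggregates cross-cohort results by
   the test subject's 10-meter-walk-test stratum (mild > 0.8 m/s, moderate
   0.4–0.8, severe < 0.4). Environmental designs use the merged four-class
   problem (Sitting+Lying → Sedentary, the two stair directions → Stairs) on
   the pool of subjects with at least 60 s of every activity in every session;
   personal Home-to-Home uses four chronological folds with boundary-straddling
   clips dropped, so no raw sample is shared between folds. Mean recall is the
   unweighted mean over classes present in the test set; absent classes are
   omitted rather than scored zero, which matches per-subject averaging and
   keeps the paired t-tests well-defined.

## The synthetic-data generator

No sensor recordings are deposited for this study design, so
`simulate_cohort` generates them. Signals are synthesized in a body frame
(x forward, y lateral, z vertical) and rotated by a per-subject random phone
orientation, because the pouch position was unconstrained in the emulated
protocol; orientation-robustness of features is therefore exercised by
construction.

* **Stationary activities**: gravity (9.81 m/s²) along an activity-specific
  orientation plus band-limited sinusoidal postural sway (0.1–0.8 Hz,
  SD 0.018–0.035 m/s² by activity) and a small white sensor-noise floor.
* **Gait**: quasi-periodic vertical, fore-aft and lateral components at the
  cadence and its harmonics. Cadence = 0.5 + 1.2·v Hz and amplitude =
  1.8·v m/s² for gait speed v (stairs slightly slower and asymmetric);
  stride-to-stride variability scales as 0.06/(0.25 + v), so slow (severely
  impaired) walking is low-amplitude, low-cadence and more variable — the
  generative mechanism behind ambulatory→stationary confusion.
* **Stairs**: a signed barometric trend of 0.12 hPa per vertical meter at a
  climb speed of 0.25·v m/s (pressure falls on ascent), over a 6-Hz barometer
  with 0.03 hPa noise and slow drift.
* **Home sessions**: an environment-variability multiplier (default 1.6)
  inflates sway, adds per-bout orientation jitter and log-normal amplitude and
  effective-speed jitter, and shifts class prevalence (more sitting and
  walking, few stair bouts). Lab sessions draw from the same distribution on
  both visits, which is what makes Lab1→Lab2 transfer succeed while
  Lab1→Home degrades.
* **Protocol imperfections**: per-bout phone-handling artifacts (1–3 s
  broadband noise at the edges), label swaps, and bout drops, at configurable
  rates (defaults 0.3 / 0.02 / 0.05), with ground truth retained for test
  assertions.

All coefficients are synthetic stand-ins — the emulated study reports no
signal-level measurements — and are exposed via `activity_params` and
`cohort_spec`. What passing tests show is that the *analysis* behaves
correctly and reproduces the qualitative phenomena the generator encodes
(impairment-dependent confusion, lab-to-home shift, barometer utility); they
cannot certify performance numbers on real stroke data.

Default cohort sizes are desk-scale: 8 healthy subjects and 8 per stroke
impairment stratum, roughly 40 bouts per subject, with bout durations of
11–30 s by activity. The emulated study's size (15 healthy; 8/13/9 stroke) is
one constructor call away and is used in the manifest test.

## Numerical choices

* Skew and kurtosis are population (biased) moments, kurtosis non-excess;
  degenerate signals (zero variance) yield 0 for z-scores, skew, kurtosis and
  correlations, so constant clips produce defined features rather than NaN.
* The z-score histogram uses four equal bins on [−2, 2] (last bin closed),
  reported as fractions of the clip length.
* "Normalized" cross products divide the mean product by the product of the
  axis RMS values (bounded in [−1, 1], distinct from mean-centered Pearson r);
  absolute variants take |a·b| before averaging.
* The power spectrum is the one-sided periodogram of the mean-removed clip
  (0.1 Hz resolution at 10 s / 50 Hz); spectral moments are computed over all
  positive-frequency ordinates up to 25 Hz, and each 0.5-Hz band power is the
  mean of its five ordinates (the DC ordinate, zero after mean removal,
  belongs to the first band). Whether the original analysis truncated the
  moment range at 10 Hz is unknown; the full range is used here.
* The derivative is the first difference divided by the sample period.
* The mean squared norm is invariant under global rotation of a clip and is
  property-tested as such. The sum of axial SDs is *not* rotation-invariant
  (the sum of variances is, the sum of SDs is not); it is implemented exactly
  as defined and not claimed invariant.
* Sample entropy counts both template lengths over the same N − m start
  positions, so constant series give exactly 0; the no-match case returns
  +Inf as a sentinel.
* Duplicated timestamps keep the first occurrence; bout intervals are
  half-open [start, end).
* Undersampling with replacement is used only when a class is smaller than
  the per-class target, keeping iterations well-defined on tiny strata.
* rpart caps tree depth at 30; with 10-s clips and minimum leaf 5 this cap
  does not bind at the problem sizes used here.

## Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline on synthetic
cohorts of 8 subjects per stratum with ~40 bouts each for the population and
impairment contrasts, and a 6-subject three-session cohort (30 bouts per
session, at least 5 bouts per activity, no simulated data loss, so the
60-s eligibility rule is satisfiable by construction) for the environmental
contrast; qualitative checks run over five generator seeds. Design models in
these checks use 10 boosting rounds — the contrasts of interest are large and
stable at that size — while the package default remains 200. The learning
curve defaults to 100 repetitions (configurable) rather than the 1000 used in
the emulated analysis; the 1200-instance constant training size is kept.

## Known limitations

* Generator realism: sinusoidal sway, phase-jittered harmonic gait and a
  linear barometric trend capture the discriminative structure, not
  biomechanics; real phone data have richer noise (pocket vs pouch, screen
  interactions, temperature-dependent barometer drift).
* The mislabel filter only catches flat-signal ambulatory labels, as in the
  emulated protocol; stationary-label swaps pass through.
* Eligibility, prevalence and session structure are bout-level abstractions;
  real free-living data have no bout boundaries.
* Absent-barometer clips carry NA barometer features, which the modelling
  layer imputes as 0 (uninformative) rather than dropping the instances.
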