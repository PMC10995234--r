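---
title: "Motion-based cough detection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based cough detection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cough is a cardinal symptom of chronic respiratory disease, and most
automatic cough detectors listen for it with always-on microphones —
effective, but privacy-invasive. An alternative is to detect the *motion*
of coughing: the inspiration–compression–expulsion motor pattern of a
cough produces a characteristic transient in a chest-worn tri-axial
accelerometer. `coughmotion` implements a complete, tested analysis
pipeline for evaluating how well simple time-domain features of short
accelerometry windows separate cough from non-cough activity:

1. a synthetic cohort generator standing in for unreleased subject
   recordings,
2. preprocessing (vector magnitude, band-pass filtering, record-level
   train/test split, sliding-window segmentation, per-window centering),
3. 43 time-domain features per window,
4. 11 feature-importance rankings, and
5. top-k ridge-logistic classification evaluated under a
   subject-record-split and a leave-one-subject-out (LOSO) protocol,
   with the full set of confusion-matrix metrics.

## The synthetic cohort

No public recordings exist for this problem at the cohort structure the
pipeline targets, so the generator in `simulate_cohort()` produces a
statistically structured stand-in: 5 subjects, 180 ten-second recordings
at 62.5 Hz (90 cough / 90 non-cough; four subjects contribute 20 + 20,
one 10 + 10).

A cough record is baseline sensor noise plus a train of three-phase
bursts: a quiet inspiratory ramp (0.4 s, peak 1/16 of the burst
amplitude), a near-zero compression pause (0.1 s), and a high-amplitude
expulsive transient — a Hann-windowed damped sinusoid (0.35 s, 8–14 Hz,
inside the analysis pass band) with lognormal amplitude jitter and
random polarity. Cough sessions are modelled as *continuous repeated
coughing*, so the default 6–9 bursts are laid out on a jittered grid
covering the whole record; every 2 s window of a cough record then
contains cough motion, which is what makes window-level labels
meaningful. Onset jitter keeps the train non-periodic. The burst gain is
largest on the z axis (anterior–posterior chest motion), intermediate on
y, smallest on x (`axis_gains = c(0.35, 0.6, 1.0)`), so magnitude- and
z-axis features should dominate the rankings qualitatively.

A non-cough record is baseline noise plus a slow postural drift
(0.05 amplitude at 0.1–0.4 Hz, i.e. below the 0.5 Hz band edge, removed
by the filter) and, in half of the records, a low-amplitude "talking"
tremor at 4–8 Hz. Every record of a subject is scaled by a lognormal
per-subject gain (sd 0.15), so absolute amplitude cues are partially
confounded with subject identity — deliberately, because that is what
makes LOSO harder than the record split on real data.

Default amplitudes (arbitrary units; think g): noise sd 0.02, burst
peak 0.8, tremor 0.004. Two properties anchor these choices rather than
any claim of physiological fidelity:

* at the defaults the classes are strongly separable end-to-end
  (baseline LOSO accuracy well above 0.9), so the downstream stages are
  genuinely exercised;
* the class contrast is carried by the burst train alone: when
  `burst_peak_amp` is set equal to `noise_sd` the end-to-end accuracy
  collapses to chance. This is why the tremor default sits below the
  noise floor — non-cough-specific motion must not become an independent
  class cue, and real collar-clip talking vibration is subtle in any
  case.

What the generator does **not** emulate: real cough kinematics and
inter-subject morphology differences, sensor saturation, orientation
changes, gravity components, or structured daily-living activity.
Passing tests on this cohort therefore demonstrate that the pipeline's
machinery is correct and information-efficient, not that any particular
accuracy will transfer to real recordings.

Each record is drawn from its own RNG substream derived from the global
seed and a record counter, so cohorts are bit-reproducible and a
record's samples do not depend on generation order.
`simulate_feature_table()` additionally provides a direct fixture for
the ranking/evaluation stages: balanced labels, a chosen number of
class-shifted Gaussian features (default effect size 2 sd) among pure
noise columns.

## Preprocessing

The pipeline order is fixed: magnitude → filter → split → segment →
center.

* **Magnitude.** `Mag = sqrt(x^2 + y^2 + z^2)` per sample, computed on
  the raw axes before filtering, giving a fourth, orientation-free
  channel.
* **Band-pass filter.** Fourth-order Butterworth, 0.5–15 Hz, applied
  forward and backward (zero phase; the effective order doubles). The
  high-pass edge removes DC offset and postural drift, the low-pass
  edge removes content above the band where cough transients
  concentrate. Since this is an offline analysis, zero-phase filtering
  is preferred over causal filtering to avoid phase distortion of the
  burst morphology. The implementation uses odd extension at both ends
  (pad length `3 * (filter length - 1)` = 24 samples) with steady-state
  initial conditions, so a constant input maps to numerical zero and
  boundary transients are suppressed; the IIR kernel (direct form II
  transposed) is compiled code. Boundary samples of a 10 s record are
  still the least trustworthy part of the output — frequency-response
  checks in the tests trim 1 s from each end before comparing against
  the analytic response.
* **Record split.** Within each (subject, class) stratum, record ids
  are shuffled with the split seed and `round(0.8 * n)` go to training.
  On the default cohort this is exact: 144 training and 36 testing
  records, balanced between classes within every subject.
* **Segmentation.** Window length `round(2 s * fs)` = 125 samples; step
  `floor(0.2 s * fs)` = 12 samples. The floor is deliberate: 62.5 Hz ×
  200 ms = 12.5 samples is not integral, and a 12-sample step is the
  unique choice reproducing 42 fully contained windows per 10 s record
  (a 13-sample step would give 39). Partial windows at the record end
  are not emitted and not padded. 42 × 144 = 6048 training and
  42 × 36 = 1512 testing windows.
* **Centering.** Each window channel has its own mean subtracted
  (idempotent), so amplitude features measure deviation rather than
  posture offset, and RMS equals the standard deviation exactly.

## The 43 features

Ten statistics on each of the four channels, plus three inter-axis
correlations, named `Min_X … MAD_Mag, Corr_xy, Corr_yz, Corr_xz` in a
fixed registry order (`feature_names()`). Conventions that matter:

* **Population (biased) moments** throughout, so the centered-window
  identities `RMS = sd` and `Var = RMS^2` hold exactly; skewness is
  `m3 / m2^1.5`, kurtosis is Fisher's `m4 / m2^2 - 3`.
* **IQR** uses linear interpolation between order statistics (R
  quantile type 7, the convention of common dataframe tooling); **MAD**
  is unscaled `median(|x - median(x)|)`.
* **Approximate entropy** (`Ent_*`): ApEn with Chebyshev distance and
  self-matches included, tolerance `r = 0.2 * sd` recomputed from each
  window's own (population) sd, estimated for embedding dimensions
  0..2 and averaged, with `phi_0 := 0` so the dimension-0 term is
  `-phi_1`. The per-dimension estimates telescope, so the mean is also
  `-phi_3 / 3`; the implementation computes the correlation-sum logs in
  compiled code and is verified against a brute-force template-counting
  oracle. A zero-variance channel returns 0 (no structure to measure,
  and the tolerance would be 0/ill-defined). Both parameters are
  exposed (`extract_features(windows, apen_m, apen_r)`).
* **Correlations** are Pearson within the window (Spearman is reserved
  for the target-correlation *ranking*, where it is the appropriate
  choice against a binary target); a zero-variance channel yields 0.

Degenerate windows therefore never produce missing values: constant
channels give 0 for skewness, kurtosis, entropy and correlation, and 0
dispersion, so the feature table is always complete.

## The 11 rankings

All rankings are computed from the training windows only and return a
full permutation of ranks 1..43 (1 = most important). Ties are broken
everywhere by registry order, which makes every method deterministic
given its seed.

* **XGBoost / DT / RF** — built-in importances of gradient boosting
  (total gain, 100 rounds), a single decision tree (summed Gini
  improvement of its primary splits, grown with scale-free stopping
  rules so the ranking is invariant to duplicating the table), and a
  random forest (mean decrease in Gini impurity, 100 trees — the common
  default forest size in the ecosystem the other importance methods
  come from). Features a model never uses score 0.
* **PC1** — absolute loadings of the first principal component,
  computed on standardized features by default (an `standardize =
  FALSE` switch exists because the choice is genuinely open: PCA on raw
  covariance lets high-variance features dominate). Explained-variance
  ratios are attached for inspection.
* **LOO** — leave-one-*feature*-out: base 5-fold stratified CV accuracy
  of the ridge-logistic estimator on all 43 features minus the CV
  accuracy without the feature. The same fold assignment is reused for
  every feature, so comparisons are paired; standardization statistics
  are recomputed inside each CV fold. CV accuracy is used rather than
  training accuracy to avoid ranking by optimism.
* **PERM** — permutation importance: the estimator is fitted once on
  all features, then each column is shuffled 10 times and the mean
  accuracy drop on the fitted table is the score. (The fit-once
  contract precludes CV scoring here; shuffling a constant column
  yields exactly zero drop.)
* **RFE_10/20/30/43** — backwards elimination with the ridge-logistic
  estimator on standardized features, dropping the smallest-|coefficient|
  feature one at a time. All four variants share one deterministic
  elimination path, which makes their top sets nested by construction.
  Eliminated features are ranked worst-first by elimination order;
  survivors are ranked by |coefficient| of the fit on exactly the
  surviving set. At `rfe_n = 43` nothing is eliminated and the ranking
  is the |coefficient| order of a single fit — a documented
  reconstruction, since an elimination-only definition degenerates
  there.
* **Corr** — absolute Spearman rank correlation of each feature with
  the binary target; invariant under monotone feature transforms;
  zero-variance features score 0.

The wrapper methods (LOO, PERM, RFE) deliberately use the *same*
classifier as the final evaluation so that rankings and evaluation
optimize the same model family. `rank_all()` returns all eleven;
`ranking_matrix()` and `topk_membership()` export the 43 × 11 rank
matrix and the top-10/20/30 membership table.

## Classification and evaluation

The classifier is an L2-regularized (ridge) binary logistic regression,
fitted by glmnet at the single penalty `lambda = 1 / (n * C)` with
`C = 1` — the glmnet-scaled equivalent of a fixed-strength penalty
`||w||^2 / 2` — on features standardized with training-set statistics
only. The decision threshold is fixed at probability 0.5; no threshold
tuning is in scope. Ridge regularization also keeps the fit well-defined
when classes are linearly separable, where unpenalized logistic
regression diverges.

Two protocols:

* **Record split** — rankings computed once on the 6048 training
  windows; for each of the 11 methods and each k in {10, 20, 30}, the
  classifier is trained on the training windows restricted to the top-k
  features and scored on the 1512 test windows; plus one all-features
  baseline: 34 models.
* **LOSO** — one fold per subject (5 folds); each fold re-ranks all 11
  methods on its own training windows by default (`loso_rank =
  "per_fold"`), so feature selection never sees the held-out subject; a
  `"global"` mode reusing record-split rankings exists because the
  original protocol is ambiguous on this point. Per (method, k) the
  summary reports the arithmetic mean of each metric across folds
  (matching the average-across-folds convention) together with the
  summed confusion counts and, for transparency, metrics pooled over
  those summed counts (`pooled_*` columns) — the metric identities hold
  exactly on per-fold and pooled rows, but not on fold-averaged
  metrics, which is why both are emitted. A fold whose held-out subject
  has single-class windows is flagged `degenerate_fold`. Another 34
  models, 68 in total.

Nine metrics are computed from the confusion counts with cough as the
positive class: ACC, SN, SP, PPV, NPV, F1, FPR, FNR, FDR. Zero
denominators return 0 with a `degenerate` attribute rather than NaN.
The one subject contributing half as many records as the others makes
LOSO fold sizes uneven; per-fold results are exposed so that effect is
inspectable, but folds are not reweighted.

## Reproducibility and problem sizes

`run_pipeline(seed)` derives every stage seed deterministically from the
global seed, and writes (when given an output directory) the cohort
CSVs, feature tables, rank matrix, membership table, results, per-fold
results and a JSON manifest. Two runs with the same seed are identical.

The default problem sizes are the cohort's own: 180 records, 7560
windows, 43 features, 11 rankings, 68 models. The test suite runs the
full default pipeline once and reuses it across checks; unit tests use
smaller fixtures (hundreds to two thousand rows) chosen so every
statistical property they assert is stable at a fixed seed.

## Known limitations

* The generator is a structural stand-in; none of its amplitude
  parameters are claims about real coughs, and reported accuracies on
  synthetic cohorts do not predict performance on real recordings.
* Tree growth details (stopping rules, tie handling) differ across
  libraries, so single-tree rankings are comparable in spirit across
  toolchains, not numerically portable.
* The permutation ranking scores on the table the model was fitted to;
  with a strongly regularized linear model this optimism is mild, but
  it is a convention, not the only defensible one.
* LOSO re-ranking multiplies ranking cost by the number of folds; the
  LOO ranking (44 × 5 CV fits per call) dominates the end-to-end
  runtime.
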