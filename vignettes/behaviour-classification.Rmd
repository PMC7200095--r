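---
title: "Classifying animal behaviour from burst accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying animal behaviour from burst accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accbehav)
```

## The data model

The unit of data is the **burst**: one short recording interval of a
tri-axial collar accelerometer, by default 110 samples per axis at
33.33 Hz (3.3 s), recorded every two minutes rather than continuously.
Axes follow the collar convention x = sway, y = surge, z = heave.
Acceleration stays in device units throughout: every downstream feature
is either scale-free or consistently scaled, so calibration to m/s²
would change nothing the classifiers see.

Training data are bursts paired with a behaviour label from a closed
**ethogram** (here: feeding, grooming, resting, caching, trotting,
walking), linked by exact timestamp match between the observation log
and the burst start after a user-supplied per-collar clock offset.
Collar clocks drift; correcting that drift is a human-in-the-loop
judgement made against observed behaviour changes, so the package
deliberately exposes only a constant offset rather than automating the
correction. Observations listing more than one behaviour mark mixed
bursts, which are excluded entirely — a burst straddling a behaviour
change is characteristic of neither class. All exclusions and drops are
counted in a structured run log; nothing is dropped silently.

## Moving-window augmentation

Ground-truthed burst data sets are small (thousands of bursts), which
starves data-hungry classifiers. The moving window turns each burst of
$n$ samples into all $n - w + 1$ contiguous windows of length $w$
(step 1): 32 windows per 110-sample burst at $w = 79$. Unlike random
sub-sampling, this preserves sample order, which the FFT predictors
require. Two consequences drive design decisions elsewhere:

* **Leakage.** Windows from one burst are near-duplicates, so the
  train/test split must happen at burst level, per class, *before*
  windowing. `stratified_split()` enforces this; per-class training
  counts are round-half-up of 0.7 times the class count, with at least
  one test burst forced per class.
* **Ensembling.** At prediction time a burst's windows vote; the
  absolute majority (> 50%) wins, and the absence of an absolute
  majority is itself treated as a rejection. The vote fallback is not
  externally specified anywhere; rejection is the conservative choice
  consistent with the threshold's purpose, and `burst_vote()` implements
  exactly that.

## The predictor set

Per window and axis: mean, standard deviation, inverse coefficient of
variation (mean/sd), variance, skewness and kurtosis. Moments are
population moments (divide by $n$); skewness and kurtosis are the
standardized third and fourth central moments, with kurtosis left
un-excess-corrected. These conventions are fixed for reproducibility —
sample-vs-population and excess-vs-raw variants differ only by smooth
monotone transformations that classifiers absorb. For a constant window
(sd = 0, e.g. deep rest), inverse CV, skewness and kurtosis are mapped
to 0 so that feature vectors stay finite; this sentinel is the only
place the features are not a literal formula evaluation.

Across axes: $q$ = mean per-sample vector norm; pitch =
atan2(ȳ, √(x̄² + z̄²)) and roll = atan2(x̄, √(ȳ² + z̄²)) in degrees,
computed from the window means as the static (gravitational) component;
and ODBA, the mean summed absolute deviation of each axis from its
window mean. The ODBA static component is the window mean rather than a
running mean: on windows of at most 3.3 s there is no meaningful
smoothing span to estimate. The exact published formulations of q,
pitch and roll vary between sources; the expressions above are this
package's declared conventions, not claims about any particular one.

Finally the full one-sided FFT magnitude spectrum of each axis (length
⌊w/2⌋ + 1 including DC, no taper, no normalization) restores the
within-window temporal structure the summary statistics discard. At
$w = 79$ the vector is 3·6 + 4 + 3·40 = 142 predictors; the column
order is frozen (`feature_names()`) and carried in the feature-table
header for model portability.

## Classifiers, rejection and voting

Three back-ends share the surface `train_model()` / `predict_probs()`:

* **SVM**, radial kernel (e1071), pairwise-coupling probabilities.
* **Random forest**, 500 trees (randomForest), tree-vote fractions.
* **Neural network**: a three-layer feed-forward net — input, one
  rectifier hidden layer of width max(64, 2·classes), softmax output —
  trained by mini-batch Adam on the cross-entropy with a fixed epoch
  budget (30), batch 256, learning rate 1e-3, weight decay 1e-4, all
  seeded. The network is implemented in the package as plain matrix
  algebra: the configuration above (rectifier activation, epoch-based
  stochastic training) is the intended design, and writing it directly
  keeps training deterministic given the seed and free of heavyweight
  dependencies.

Features are z-scored using training-split statistics for the SVM and
the network; the forest is scale-invariant and takes raw features.
Class imbalance (resting dominates captive data roughly 13:1 over
walking) is deliberately **not** reweighted by default — the natural
prior is part of the signal — but class weights are exposed.

A window is assigned its most probable class only when that probability
*strictly exceeds* τ (default 0.7); otherwise it becomes `"other"`.
The threshold exists because captive animals do not exhibit the full
wild repertoire: behaviours missing from the ethogram, and mixed
bursts, should surface as low-confidence assignments rather than
confident mislabels. Thresholding is monotone: raising τ can only move
windows into the rejection class, never out of it.

## Window-size selection

`sweep_window_sizes()` evaluates each candidate size with the same
burst-level split: expand, train, then score the *test windows* (each
window one item — burst-level voting is a separate, later step). The
score is the mean of mean recall, mean precision and 1 − rejected
proportion, all on [0, 1]. Accuracy is computed but excluded from the
score: with strong imbalance its true negatives are dominated by the
resting class and it flatters every other class.

`smooth_and_select()` fits a penalized cubic regression spline
(mgcv GAM, basis dimension 40 by default, capped at the number of
points minus one; smoothing parameter by GCV), normalizes the fitted
curve to [0, 1], and computes difference-quotient slopes — central
differences at interior sizes, one-sided at the ends. Central
differences are used because they vanish exactly at a discrete
symmetric peak, which is what "slope close to zero at the optimum"
means on a grid. The chosen window is the smallest size whose fitted
value is within `slope_tol` (default 1e-3) of the fitted maximum *and*
whose |slope| ≤ `slope_tol`; plateaus therefore resolve to their
smallest member (smaller windows are preferred: more augmentation, and
any mixed-behaviour contamination occupies a larger fraction of a
smaller window). If nothing qualifies — e.g. a strictly rising curve —
the argmax is returned. A fitted range at numerical noise level
(≤ 1e-9 relative) is treated as flat rather than normalized into fake
structure.

## Field validation without ground truth

Four indirect checks assess whether wild-animal assignments are
credible:

1. **Diel composition** (`diel_composition()`): assignment counts per
   month × time-of-day bin × behaviour. Months with under 15 distinct
   days of data are flagged as uninterpretable. Bins default to 30 min;
   time of day uses a configurable UTC offset because tag clocks run
   UTC while activity patterns are local.
2. **GPS clusters** (`segment_clusters()`,
   `cluster_behaviour_coherence()`): a single pass groups consecutive
   fixes within 50 m of the cluster's first fix; a fix beyond 50 m
   anchors the next cluster. Assignments map to clusters by time span
   (anchor to last member, half-open on the right — the mapping of
   bursts to clusters is a package convention, since bursts and fixes
   are recorded on independent schedules). Only clusters holding at
   least 10 assignments qualify, so travel tracks of singleton clusters
   cannot count as "clustered". Stationary behaviour (resting) should
   score high, locomotion low.
3. **Speed coherence** (`gps_speed()`,
   `match_speed_to_behaviour()`): speeds are haversine distance over
   time between consecutive fixes (sphere radius 6371.0088 km — at
   50 m scales the ellipsoid is irrelevant); assignments within 10 s of
   a fix (boundary closed) join that interval's speed. Resting should
   be slower than trotting; the classical two-sample Wilcoxon rank-sum
   test quantifies this.
4. **Actograms** (`actogram()`): day × time-of-day rasters of burst
   ODBA or a behaviour indicator, with sunrise/sunset overlays from the
   standard NOAA low-accuracy solar algorithm (a couple of minutes'
   accuracy, ample for plots). High-ODBA times should coincide with
   locomotor assignments.

## The synthetic generator

Every class is an additive signal: static orientation + optional
sinusoidal gait component (frequency, amplitude, fixed axis weighting
sway:surge:heave = 0.2:0.6:1.0, random phase, ±20% per-burst amplitude
jitter) + Gaussian noise. Defaults: resting is still and quiet
(noise sd 0.02); grooming is broadband noise (sd 0.5) without
periodicity; walking ≈ 1.5 Hz at moderate amplitude; trotting ≈ 3 Hz at
high amplitude; feeding and caching are intermediate (1 and 2 Hz).
These were chosen once so that moment, posture and spectral features
can separate the classes — walking/trotting stride rates in the 1.5–3 Hz
range are typical for a mid-sized cursorial mammal, and the FFT bin
spacing at w = 79 and 33.33 Hz (0.42 Hz) resolves them.

The captive generator defaults to the imbalanced class counts of a
realistic ground-truthed set (feeding 367, grooming 1140, resting 2114,
caching 197, trotting 179, walking 162; 4159 bursts). The wild
generator simulates a 7-day individual: a per-hour diel schedule
(resting by day, trotting-dominated nights, mixed crepuscular hours)
with bout persistence (probability 0.9 of repeating the previous
2-minute state — a simple sticky-state process, not a full semi-Markov
model, but enough to create realistic GPS clusters), a position process
with per-state speed ranges (trotting 1.8–3.0 m/s > walking
0.7–1.3 m/s > resting ≈ 0), resting bouts confined to a 15 m dwell
radius, and GPS fixes every 4 minutes. Truth labels are returned
separately from the emitted data.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: inter-individual variation, collar
slip and orientation drift, behaviours outside the ethogram, gradual
transitions and within-burst mixtures (available only via the explicit
mixed-burst option), GPS error, terrain, and the captive-to-wild domain
shift that is precisely the hard part in the field. On this generator
the captive-validation and wild-recovery kappas are essentially
perfect; that is a correctness check of the pipeline machinery, not a
performance claim. Real transfers degrade — notably, classifiers
without the windowing/thresholding machinery can collapse to a single
predicted class on out-of-domain data, which is why the validation
procedures exist.

## Numerical choices and degenerate inputs

* Probability rows must sum to 1 within 1e-6; the threshold comparison
  is strict (`>` τ), so τ = 0 disables rejection-by-threshold but not
  rejection-by-tie.
* Ties in `max.col` are broken by first index; vote ties return the
  rejection class.
* Cohen's kappa uses the standard marginal chance term
  pₑ = Σ (row/n)(col/n). A variant substituting (TP+TN)/n for the truth
  margin appears in some write-ups; it is exposed behind
  `chance = "tn_product"` but is not the default, as the marginal
  product is the conventional two-rater definition.
* Constant windows produce sentinel moments (see above); an all-zero
  mean vector makes pitch/roll an error rather than a silent 0.
* Bursts shorter than the window are skipped and logged at prediction
  time; bursts of differing lengths in one feature table are an error
  (feature dimensionality must be constant).

## Problem sizes in the packaged checks

The test suite and the acceptance script run the full-size recovery
experiment (4159 captive bursts → 133 088 windows at w = 79; a 7-day
wild track of 5040 bursts) once, and use reduced sizes elsewhere: the
window-size sweep runs on 105 bursts over sizes 20–110 in steps of 10
with a 10-epoch network, which is ample to exercise the machinery; the
selection rule itself is additionally verified against an analytic
parabola where the correct answer is exact.

## Known limitations

* Exact-timestamp label matching assumes the clock offset fully
  resolves drift; there is no fuzzy-match tolerance.
* The burst-to-cluster mapping and the speed-interval join are temporal
  conventions; with sparse GPS schedules most bursts are unmatched for
  the speed check (by construction, only bursts within 10 s of a fix
  qualify).
* The SVM probability calibration (pairwise coupling) involves an
  internal cross-validation; it is seeded and reproducible but can be
  slow on very large window tables.
* Sun times use a spherical low-accuracy algorithm; do not use them
  for anything beyond plot overlays.
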