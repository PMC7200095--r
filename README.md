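# accbehav

Behaviour classification from burst-mode tri-axial accelerometry, with
indirect field validation for animals that cannot be observed.

## The problem

Collar-mounted accelerometers record short fixed-length *bursts* of
tri-axial acceleration (canonically 110 samples per axis at 33.33 Hz,
i.e. 3.3 s, every two minutes). Supervised behaviour classification
needs every burst paired with a directly observed behaviour label — easy
in captivity, usually impossible in the wild. `accbehav` implements a
workflow for transferring classifiers trained on observed (captive)
individuals to free-ranging conspecifics, for users in movement ecology
and biologging:

1. **Moving-window augmentation.** Each burst of *n* samples yields all
   *n − w + 1* contiguous windows of length *w* (step 1), multiplying
   the training set while preserving sample order (110 samples at
   *w* = 79 give 32 windows per burst).
2. **A fixed predictor set** per window: per-axis mean, sd, inverse
   coefficient of variation, variance, skewness, kurtosis; the
   three-axis summaries *q* (mean vector magnitude), pitch, roll and
   ODBA, where ODBA = mean over samples of |x−x̄| + |y−ȳ| + |z−z̄|;
   and the full one-sided FFT magnitude spectrum of each axis
   (142 predictors at *w* = 79).
3. **Three classifier back-ends** behind one surface: radial-kernel SVM,
   random forest (500 trees), and a three-layer feed-forward neural
   network (rectifier hidden layer, softmax output). A probability
   threshold (default τ = 0.7) rejects low-confidence windows into an
   `"other"` class; an absolute-majority vote over a burst's windows
   yields one behaviour per burst.
4. **Window-size selection**: performance (mean recall, mean precision
   and 1 − rejected proportion, averaged) is swept over window sizes,
   smoothed with a penalized-spline GAM (k = 40), and the smallest
   window whose fitted score sits at the maximum with near-zero slope is
   chosen.
5. **Four field-validation procedures** for unobservable animals: diel
   behaviour composition by month, coherence with sequential 50 m GPS
   clusters, coherence with GPS-derived speed (resting should be slow,
   trotting fast; Wilcoxon rank-sum), and day × time-of-day actograms of
   ODBA or behaviour with sunrise/sunset overlays.

Evaluation uses per-class recall, precision, accuracy and Cohen's kappa,
κ = (p₀ − pₑ)/(1 − pₑ) with p₀ the observed and pₑ the chance agreement
from the confusion-matrix margins.

A synthetic-data module generates labelled captive-style bursts and
wild-style burst + GPS streams with known ground truth, so the whole
pipeline is testable without any field data.

## Worked example

```r
library(accbehav)
captive <- generate_captive_dataset(
  counts = c(feeding = 30, grooming = 60, resting = 120, caching = 20,
             trotting = 20, walking = 20), seed = 1)
plan  <- window_plan(79)
split <- stratified_split(captive, train_frac = 0.7, seed = 2)
train <- expand(split$train, plan)
test  <- expand(split$test, plan)
model <- train_model(train, train$label, model_spec("ann", seed = 3))
performance_report(test$label,
                   apply_threshold(predict_probs(model, test), 0.7))
#> Performance report
#>     class recall precision accuracy
#>   caching      1         1        1
#>   feeding      1         1        1
#>  grooming      1         1        1
#>   resting      1         1        1
#>  trotting      1         1        1
#>   walking      1         1        1
#> kappa = 1.000 | other proportion = 0.000 | selection score = 1.000
```

Held-out windows of the synthetic captive set are classified perfectly —
the generator's classes are well separated by design; real data are
harder (see the vignette). Transferring to a simulated wild individual
and checking GPS coherence:

```r
track <- generate_wild_track(wild_scenario(days = 1), seed = 4)
preds <- predict_bursts(model, track$bursts, plan, tau = 0.7)
table(preds$behaviour)
#>  caching  feeding grooming  resting trotting  walking
#>       55       95       51      260       80      179
clusters <- segment_clusters(track$gps, radius_m = 50)
cluster_behaviour_coherence(preds, clusters, min_items = 10)
#>   behaviour n_total n_in_cluster  proportion
#> 1   caching      55            1 0.018181818
#> 2   feeding      95            3 0.031578947
#> 3  grooming      51           39 0.764705882
#> 4   resting     260          252 0.969230769
#> 5  trotting      80            0 0.000000000
#> 6   walking     179            1 0.005586592
```

Resting assignments concentrate inside stationary GPS clusters (0.97)
while trotting assignments almost never do — the signature a credible
classification should show. (Grooming also clusters here because the
simulated animal grooms at its resting sites.)

A command-line interface wrapping the same functions is installed at
`inst/cli/accbehav` with subcommands `simulate`, `train`,
`select-window`, `predict`, `evaluate` and `validate`.

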