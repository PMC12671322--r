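# seizr — cross-database epileptic seizure detection from long-term EEG

Automated seizure detection turns hours of multi-channel scalp EEG into a
short, reviewable list of events, which is what makes remote monitoring of
people with epilepsy practical. The hard part is not fitting a classifier
to one hospital's recordings — it is making the same trained model work on
EEG from a *different* site, where amplifier gains, reference montages and
sampling rates shift every feature distribution. `seizr` implements a
deliberately small detection model built around that problem, plus the
synthetic multi-site corpus generator and the cross-site evaluation
harness needed to study it at desk scale.

## The model

Each channel of a recording is cut into non-overlapping 10 s epochs, and
every `(epoch, channel)` cell is classified independently:

1. **Two features per epoch.**
   - *Successive decomposition index (SDI)*: truncate the epoch to
     `N' = 2^⌊log2 N⌋` samples and run a Haar-style cascade — at each
     level form pairwise half-sums `s = (a+b)/2` (passed to the next
     level) and half-differences `d = (a−b)/2`. With mean absolute detail
     `D_k` at level `k`,

     `SDI = log2(1 + (1/L) Σ_k D_k)`, `L = log2 N'`.

   - *Matrix determinant (MD)*: reshape the first `m²` samples
     (`m = ⌊√N⌋`) row-major into an `m × m` matrix `M` and take
     `MD = log10(1 + |det M|)`, computed in the log domain (a raw 50 × 50
     determinant of microvolt-scale data overflows doubles).

   Both features grow with high-amplitude rhythmic discharge and both
   log-compress amplitude, so a site-level gain or offset moves them by
   an approximately *additive* shift.

2. **Adaptive median feature baseline correction (AMFBC).** Per channel
   and per feature, subtract the exact median of a rolling window of the
   last `W = 60` epochs (10 minutes). Site-level additive feature shifts
   cancel; the median's 50% breakdown point tolerates the rare seizure
   epochs without any seizure gating.

3. **RBF-SVM per epoch.** Features are standardized with training-set
   statistics; an RBF support vector machine (`C = 1`, kernel width from
   the median heuristic, inverse-class-frequency weights) labels each
   epoch 0/1. Trained models serialize to a versioned, portable JSON
   artifact whose loaded predictions are bit-identical.

4. **10-tap moving average + threshold.** The binary label sequence of
   each channel is smoothed causally, `y(t) = mean(labels[t−9 … t])`, and
   epochs with `y ≥ 0.5` are merged into events — an isolated false
   positive peaks at `y = 0.1` and is discarded.

5. **Scoring.** Epoch-level sensitivity `TP/(TP+FN)` and specificity
   `TN/(TN+FP)` on the raw per-epoch labels; event-level false detection
   rate per hour (events with no ≥ 1 s overlap with truth, divided by
   duration) on the post-threshold events.

Cross-site generalization is measured by **leave-one-database-out
cross-validation**: train on all databases but one, evaluate on the
held-out one, rotate.

## Worked example

Simulate the default three-database corpus (30 min per database; 8
channels; sampling rates 256/128/64 Hz; per-database gains 1/12/90 and
offsets 0/+200/−300 µV; four planted 3–5 Hz discharges of 120–180 s at
3× background RMS), then run the leave-one-database-out experiment:

```r
library(seizr)

cfg      <- synth_config(seed = 1)
corpus   <- generate_corpus(cfg)
datasets <- corpus_features(corpus)

res <- lodo_cv(datasets, window_epochs = 60)
res$folds[, c("database_id", "sensitivity", "specificity", "fdr_per_hour")]
#>   database_id sensitivity specificity fdr_per_hour
#> 1         db1       0.969           1            0
#> 2         db2       0.957           1            0
#> 3         db3       0.942           1            0
```

Despite feature shifts far larger than the seizure/background gap, every
held-out site is classified with ≥ 94% epoch sensitivity, ~100%
specificity and no false events. Disabling the baseline correction
(`window_epochs = NA`) collapses the held-out folds to chance — the
correction, not the classifier, carries the cross-site transfer.

Train on two databases and produce the app-style report for a recording
from the third:

```r
model <- train_detector(lapply(datasets[1:2], function(d)
  labeled_features(baseline_correct(d$features, 60), d$labels)))
rep <- detect_report(generate_recording(cfg, 3, 2), model)
print(rep)
#> ==== Seizure detection report ====
#> Channels            : 8
#> Sampling frequency  : 64 Hz
#> Duration            : 1800.0 s (00:30:00)
#> Epoch length        : 10 s (180 epochs)
#> Elapsed time        : 0.267 s
#> Total seizure epochs: 511
#> Seizure events per channel:
#>   CH1        4
#>   CH2        4
#>   ...
```

All four planted seizures are recovered on every channel of the unseen
recording. `evaluate_recording()` scores such a report against ground
truth; `save_model()`/`load_model()` move trained models between
machines.

A command-line front end wraps the same functions:

```sh
exec/seizr simulate --out corpus/ --seed 1
exec/seizr train    --corpus corpus/ --out model.szm
exec/seizr detect   --input corpus/db3_rec01.edf --model model.szm --report report.json
exec/seizr evaluate --input corpus/db3_rec01.edf --truth corpus/db3_rec01_truth.csv --model model.szm
```

## Scope

`seizr` operates on EDF/EDF+ files (or its own synthetic recordings) and
deliberately implements nothing beyond the model above: no filtering or
artifact rejection, no montage re-referencing, no spectral/wavelet
feature banks, no probability calibration. See the methods vignette
(`vignettes/seizure-detection-pipeline.Rmd`) for the model's assumptions,
parameter rationale, and known limitations.
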