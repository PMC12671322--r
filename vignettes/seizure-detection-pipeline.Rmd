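---
title: "Cross-database seizure detection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-database seizure detection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seizr)
```

`seizr` detects epileptic seizures in long-term multi-channel scalp EEG
with a deliberately small model — two scalar features per 10 s epoch, a
rolling-median baseline correction, an RBF support vector machine, and a
moving-average postprocessing stage — built so that a model trained on
recordings from some sites transfers to recordings from an unseen site.
This vignette explains each stage, why its parameters are what they are,
what the synthetic corpus does and does not emulate, and where the design
was genuinely open.

## The epoch as the unit of analysis

Recordings are segmented per channel into non-overlapping 10 s epochs;
each `(epoch, channel)` cell is an independent classification example.
Non-overlapping windows keep the "total seizure epochs" accounting simple
and make the per-channel event report unambiguous. A trailing remainder
shorter than one epoch is dropped (with a warning): features are defined
on fixed-length windows and a fractional epoch would bias both. No
band-pass filtering or artifact rejection precedes feature extraction;
the model consumes raw microvolt samples.

## The two features

**Successive decomposition index (SDI).** The epoch is truncated to its
leading $N' = 2^{\lfloor \log_2 N \rfloor}$ samples, then decomposed in a
Haar-style cascade: level $k$ splits the previous level's half-sums into
pairwise half-sums $(a+b)/2$ and half-differences $(a-b)/2$. With
$D_k$ the mean absolute half-difference at level $k$ and $L = \log_2 N'$
levels,

$$\mathrm{SDI} = \log_2\!\Big(1 + \tfrac{1}{L}\sum_{k=1}^{L} D_k\Big).$$

The cascade accumulates fluctuation magnitude at every dyadic time scale,
so a high-amplitude 3–5 Hz discharge raises coarse-level details sharply.
Two structural properties matter downstream: SDI is invariant to sign
flips and to DC offsets (constants cancel in every difference), and for
large signals $\mathrm{SDI}(g\,x) \approx \log_2 g + \mathrm{SDI}(x)$ — a
multiplicative site gain becomes an approximately *additive* feature
shift.

**Matrix determinant (MD).** The first $m^2$ samples
($m = \lfloor\sqrt N\rfloor$) are reshaped row-major into an $m \times m$
matrix $M$ and

$$\mathrm{MD} = \log_{10}\big(1 + |\det M|\big),$$

evaluated in the log domain via the LU decomposition: a raw $50\times 50$
determinant of microvolt-scale data overflows double precision, and the
monotone log transform preserves the class ordering that makes the
feature useful. Since $\det(gM) = g^m \det M$, a site gain again shifts
MD almost purely additively (by $m\log_{10} g$). MD is the weaker of the
two features — adding a quasi-periodic discharge to noise changes only a
few singular values of $M$, so the seizure/background gap in MD is modest
and noisy — but it responds to DC offsets and amplitude structure that
SDI ignores.

Both definitions are concrete choices for feature families published in
more detail elsewhere; they are isolated behind `sdi()` and
`md_feature()` so either can be replaced without touching the rest of the
pipeline, and the package's invariants (finiteness, symmetry, log-scale
monotonicity, oracle agreement for small $m$) pin their behaviour.

## Adaptive median feature baseline correction (AMFBC)

EEG features shift between recording sites: different amplifiers,
references and electrode impedances produce global gain and offset
idiosyncrasies, and because both features log-compress amplitude these
appear as per-site *additive* feature offsets. AMFBC removes them by
subtracting, per channel and per feature, the exact median of a rolling
window of the last $W$ raw epoch values.

Choices and their rationale:

- **Window $W = 60$ epochs (10 minutes).** Long enough that a typical
  seizure (here up to ~3 min ≈ 18 epochs) never approaches half the
  window — the median's 50% breakdown point is the method's core
  robustness assumption — yet short enough to adapt within a recording.
- **Unconditional push.** Every epoch enters the buffer, seizure or not;
  no gating rule is needed precisely because seizures are sparse in
  long-term EEG. The corollary: if seizures ever occupy ≥ 50% of a
  window, the baseline chases the seizure level and cancels it. The
  synthetic generator therefore enforces inter-seizure gaps (below).
- **Pre-push correction.** A streamed epoch is corrected against the
  median *before* it is pushed, so a step change of $\delta$ passes
  through unattenuated at the step epoch and decays to zero once
  $\lceil W/2 \rceil$ post-step epochs fill the buffer.
- **Block-seeded cold start.** `baseline_correct()` seeds the buffer with
  the first $\min(W, T)$ epochs and corrects those warm-up epochs against
  the seeded median. The alternative — correcting warm-up epochs against
  a median of only the epochs seen so far — is strictly causal but
  fragile: a seizure beginning in the first minutes dominates the young
  buffer and subtracts itself out. Block seeding trades causality during
  the first $W$ epochs (a documented cold start) for robustness; from
  epoch $W+1$ the scheme is strictly causal. The even-count median is the
  mean of the two middle values.
- **No gain normalization.** Only the additive component is corrected;
  residual scale differences are left to the classifier's feature
  standardization.

## Classifier

Every `(epoch, channel)` cell is one example; channels share one model
(the per-channel report requires per-channel decisions, not per-channel
models). Features are standardized by training-set mean and standard
deviation, then fit with an RBF-kernel SVM:

- `C = 1` — no evidence in this problem for heavier regularization
  either way; exposed as a parameter.
- Kernel width by the **median heuristic**: $\gamma = 1/(2s^2)$ with $s$
  the median pairwise distance between standardized training rows
  (deterministically subsampled). Scale-free and reproducible.
- **Inverse-class-frequency weights** ($n / 2n_k$): long-term EEG is
  overwhelmingly non-seizure, and without weighting the all-negative
  classifier dominates the margin objective.

The trained artifact stores the standardization statistics, support
vectors, dual coefficients, intercept, decision-sign orientation and a
format version, serialized as JSON with doubles at 17 significant digits
— which round-trips IEEE doubles exactly, so a loaded model's predictions
are bit-identical. Prediction is computed from the stored parameters
directly, making the artifact self-contained and portable across
machines and languages (a deliberate contrast to language-native
pickling, which executes code on load). Loading rejects missing/unknown
versions and feature-order mismatches.

## Postprocessing and events

The classifier's binary per-channel label sequence is smoothed with a
causal 10-tap moving average (pre-recording history = 0, matching
streaming deployment), and epochs with $y \ge \theta = 0.5$ become
positive; maximal positive runs form events. $\theta = 0.5$ makes
"majority of the last 10 epochs" the event criterion: an isolated false
epoch peaks at $y = 0.1$ and vanishes, and in general runs shorter than
$\lceil \text{taps}\cdot\theta \rceil = 5$ epochs cannot produce an
event. Gaps are not merged by default (`merge_gap_epochs = 0`). Both
parameters are exposed because the causal-vs-centered choice and the
threshold are genuinely open design points.

Epoch-level sensitivity and specificity are computed on the **raw**
per-epoch labels, the event false-detection rate on the post-threshold
events. The causal filter shifts and stretches runs by up to half its
length, which would mechanically corrupt epoch-level counts; its purpose
is suppressing false *events*, and it is scored on exactly that. When a
class is absent (e.g. a seizure-free file), the corresponding rate is
reported as `NA`, never silently 0 or 1. A predicted event is true if it
overlaps any ground-truth interval by ≥ 1 s on the same channel
(channel-less truth matches all channels); several predictions over one
truth interval all count as true — no one-to-one matching.

## The synthetic corpus: what it emulates, and what it does not

`synth_config()` defaults define the package's reference cross-database
experiment: 3 databases × 30 minutes × 8 channels.

- **Background**: 1/f-shaped Gaussian noise at 30 µV RMS with
  intermittent 1–3 s alpha (10 Hz) bursts — the gross spectral shape of
  resting EEG, nothing more.
- **Seizures**: 4 per recording, 120–180 s (typical convulsive to long
  focal seizures), a 3–5 Hz rhythmic discharge with a second harmonic at
  half amplitude and 2 s linear onset/offset ramps, affecting all
  channels (generalized events). `amplitude_ratio = 3` scales the
  discharge's *RMS* to 3× the channel's background RMS, so the
  in/out-of-seizure RMS contrast is $\sqrt{1+3^2} \approx 3.2$ by
  construction regardless of harmonic content.
- **Seizure sparsity**: a ≥ 360 s gap between events (post-ictal
  quiescence at minimum), which caps any 10-minute baseline window at
  ~40% seizure — inside the rolling median's breakdown point, the
  method's stated operating assumption. Placement distributes the
  remaining slack uniformly via the sorted-uniform spacings
  construction, which is exactly uniform over feasible layouts and
  cannot deadlock the way sequential rejection sampling does under tight
  packing; infeasible configurations error out.
- **Inter-database variation is purely affine**: gains (1, 12, 90) and
  DC offsets (0, +200, −300 µV), the minimal structure AMFBC claims to
  fix. Measured on the default background at 256 Hz, the
  seizure-vs-background feature gap is ≈ 1.25 (SDI) and ≈ 2.5 (MD); the
  gain-induced feature shifts have magnitude ≈ 54 and ≈ 98 — far more
  than 5× the class gap, so an uncorrected model cannot transfer. Gains
  are kept ≥ 1 deliberately: both features compress through
  $\log(1 + \cdot)$, so a gain ≪ 1 does not shift the features, it
  crushes the class gap itself.
- **Sampling rates 256/128/64 Hz** — standard power-of-two EEG rates,
  chosen so the SDI's power-of-two truncation covers the same 8 s of
  every 10 s epoch in every database. (At 200 Hz the truncation covers
  only 5.12 s, leaving the feature blind to seizure onsets in the back
  half of an epoch — a real property of the feature worth knowing about,
  but a confound in a corpus meant to isolate affine site variation.)
- Each recording's RNG stream is seeded by a deterministic mix of the
  corpus seed and the (database, recording) indices, so corpora are
  bit-reproducible and individual recordings can be regenerated in
  isolation.

What the generator does **not** emulate: electrode artifacts (EMG, eye
blinks, electrode pops), non-stationary background drift, focal seizures
with channel-specific morphology and propagation, inter-patient
variability, or realistic seizure rates (hours-to-days between events).
Passing the package's cross-database tests therefore demonstrates that
the pipeline removes affine site variation and detects high-contrast
rhythmic discharges — it does not demonstrate clinical-grade performance
on hospital EEG, whose headline numbers require the original recordings.

## Labeling and evaluation conventions

An epoch is labeled seizure if it overlaps a ground-truth interval by at
least one sample (`min_overlap_s = 1/fs`, configurable). This any-overlap
rule is deliberately strict: epochs containing a fraction of a second of
low-amplitude onset ramp count as positives, and they are the dominant,
largely irreducible miss class in the epoch-level sensitivity of every
experiment here — a labeling artifact worth remembering when reading
sensitivity numbers near their ceiling.

In `lodo_cv()`, AMFBC runs *within* each database before the fold split
(it is a causal per-recording filter and uses no labels), training pools
all remaining databases, and the held-out database contributes nothing
to standardization, kernel width or support vectors.

## Problem sizes

The reference experiment — 3 × 30 min × 8 channels, 4320 epoch-channel
cells, one SVM per fold on ≈ 2900 standardized rows — runs in under ten
seconds on one core; the full test suite, including an exhaustive filter
oracle over all binary sequences up to length 16 and a 10,000-update
rolling-median oracle, takes on the order of a minute. These sizes were
chosen as the smallest at which the cross-database effect is
unambiguous: per-fold epoch counts in the thousands put binomial noise on
a fold's sensitivity near one percentage point.

## Known limitations

- The EDF writer requires integer sampling rates and whole-second
  durations (1 s data records); the reader handles any record duration
  but not channels with differing sampling rates in one file.
- MD contributes little discrimination on its own (see above); the
  pipeline's separation rides mostly on SDI. The two-feature design is
  kept because it is the model under study.
- Epoch-level scoring near the ceiling is governed by partial-overlap
  edge epochs, i.e. by the labeling convention rather than the model.
- The cold-start window of `baseline_correct()` is not causal (first
  `W` epochs); streaming deployments that need strict causality from the
  first epoch should warm up on a seizure-free lead-in via
  `baseline_init()` + `baseline_step()`.
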