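---
title: "Models and methods behind ctgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctgnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctgnet)
```

This vignette explains the science and the numerical choices inside
`ctgnet`: what each model assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and where the design was genuinely open.

## The classification problem

A cardiotocogram (CTG) records fetal heart rate (FHR, beats per minute,
4 Hz from clinical monitors) together with uterine activity (UC,
dimensionless tocodynamometer units). The structure obstetricians read
is episodic: *accelerations* (transient rises ≥ 15 bpm for ≥ 15 s,
reassuring), and *decelerations* classified by their timing against the
contraction — *early* (nadir at the contraction peak, benign head
compression), *variable* (abrupt, cord compression), *late* (nadir
lagging the peak by tens of seconds, uteroplacental insufficiency) and
*prolonged* (≥ 2 min). Reduced baseline variability compounds concern.
The package's target label is not a visual category but the postnatal
outcome: a delivery is **abnormal** when umbilical-artery pH < 7.20 or
the 1-minute Apgar score < 7, both strictly. The abnormal class is
positive everywhere downstream.

## Trace model and quality control

A `ctg_trace` keeps raw sample values and a validity mask side by side.
An FHR sample is invalid when it is missing, exactly zero (the dropout
sentinel used by intrapartum archives), or outside 50–210 bpm. *Signal
loss* is the invalid fraction of the FHR channel only: FHR is the
classified signal, and hospital exclusion rules quote a single loss
percentage; UC validity is surfaced but never gates a record. The
quality gate keeps records at least 30 min long with loss at most 16%,
both boundaries inclusive because the exclusion criteria are worded as
strict exceedances ("shorter than", "more than").

Two numerical choices here deserve note:

- **Windowing.** Classification uses the last 30 min before delivery.
  Recorders emit trailing runs of zero FHR after the transducer comes
  off, so the window is anchored at the last informative (nonzero,
  finite) FHR sample and time is rebased to zero. The operation is
  idempotent by construction.
- **Downsampling** from 4 Hz to the model's 1 Hz takes the mean of the
  *valid* samples in each half-open 1-s bin; an all-invalid bin yields
  an invalid output sample. Averaging, rather than decimation, uses all
  available samples and degrades gracefully under dropout; the
  alternative (taking every fourth sample) discards 75% of the data and
  propagates single-sample artifacts.

## The synthetic-data generator

Clinical CTG archives are access-restricted, so the package bundles a
simulator whose outputs are the package's study conditions. It targets
the *statistical and event structure* of intrapartum monitoring, not
cardiovascular physiology (no baroreflex, no beat-to-beat model):

- UC is a resting tone (10 units) plus a Gaussian-bump contraction train
  with ~180 s period (5% log-normal jitter), ~70 s width and amplitude
  ~40 units — ordinary active-labor values.
- FHR is a baseline drawn from the normocardic band U(110, 160) bpm,
  plus band-limited variability (white noise smoothed over ~5 s, scaled
  so that its SD is amplitude/3), plus raised-cosine episode pulses.
  Variability amplitude defaults to 10 bpm for normal and 3 bpm for
  abnormal records — moderate versus reduced variability in clinical
  terms.
- Episodes are drawn per class with Poisson counts (defaults: normal ≈ 4
  accelerations and occasional early/variable decelerations; abnormal ≈
  3 late plus 0.7 prolonged decelerations, few accelerations), with
  decelerations time-locked to contraction peaks at kind-specific lags
  (early |lag| ≤ 5 s, late lag ≥ 30–60 s). Every abnormal record is
  guaranteed at least one late or prolonged deceleration, since those
  are what define the compromised phenotype. The raised-cosine pulse
  shape was chosen because it is smooth, compactly supported and
  analytically integrable, which gives closed-form area oracles for the
  tests (area = depth × duration / 2; prolonged decelerations use a
  flat-cored Tukey shape).
- Dropout replaces an exact target fraction of samples (default 5%)
  with zero-valued invalid runs of geometric length (mean 30 s),
  mimicking contiguous transducer loss. Exactness makes the planted
  loss fraction an oracle for `signal_loss()`.

The registry generator emits a delivery cohort with *exact* stage sizes
(defaults: 5406 records; 15 stillbirths, 316 twins, 775 preterm, 619
insufficient; 298 abnormal among the 3681 kept, 136 with planted CTG
quality failures leaving 162; 617 emergency cesareans and 812 quality
failures on the normal branch leaving 1954 eligible controls — the
numbers the sorting pipeline is expected to reproduce). Group-conditional
outcomes are Normal(7.31, 0.05) vs Normal(7.25, 0.11) for pH and
rounded, clipped Normal(8.31, 0.65) vs Normal(4.30, 1.81) for Apgar,
**rejection-sampled** so each record's outcome agrees with its intended
label. Rejection is necessary, not cosmetic: the abnormal pH mean (7.25)
sits above the 7.20 threshold, so many abnormal deliveries qualify
through Apgar alone, and independent draws would contradict the labels.
A master seed is split into per-record substreams so any subset
regenerates identically.

What the simulator does **not** emulate: autonomic FHR dynamics,
sinusoidal patterns, tachysystole, drifting baselines, correlated
FHR/UC artifacts, or overlap between the classes' event distributions
beyond what the rates imply. Its default conditions are deliberately
separable. Passing benchmarks on it therefore demonstrates that the
pipeline is implemented correctly end to end — not that any model would
reach a particular accuracy on clinical data.

## The conventional chain

The baselines cannot consume 1800-sample traces, so the classical chain
reduces each record to two features:

1. **Spike removal.** "Visually evident, physiologically implausible"
   noise is not computable as stated, so it is operationalized: samples
   outside 50–210 bpm, or jumping more than 25 bpm per sample-step from
   the last accepted sample, are replaced by the mean of the nearest
   clean neighbors (nearest single value at the edges). Both thresholds
   are exposed as arguments.
2. **Smoothing.** A bilateral moving average over 15 samples — read as a
   15-point centered window (7 each side), the plain reading of
   "bilateral moving average of 15 points" — with truncated windows at
   the edges.
3. **Episode detection.** The baseline is a centered 10-min running
   median (robust to episodes, which never fill half the window at
   default rates); records shorter than the window fall back to a global
   median. The deviation from baseline is enveloped by the magnitude of
   its analytic signal (FFT construction of the Hilbert companion).
   Candidate episodes are excursions whose envelope reaches 15 bpm; each
   is refined by scanning outward **from the extremum** to the first
   sign change or zero of the deviation, classified by the deviation's
   sign there, and kept when the refined excursion lasts ≥ 15 s with
   extremum ≥ 15 bpm (standard clinical gates, which the source
   procedure leaves unstated). Two subtleties:
   - scanning outward from the run's *edges* would latch onto the
     envelope's Hilbert tails — on noiseless data the deviation is
     exactly zero outside a pulse, and the first "zero crossing" at a
     run edge is the edge itself, far from the pulse;
   - applying the amplitude/duration gates to the *refined* interval
     rather than the raw envelope run matters for threshold-amplitude
     episodes, whose envelope touches 15 bpm only at the peak.
   The running median is constant-extended from its interior rather
   than recomputed in shrinking end windows, because an episode near the
   record edge would otherwise dominate its own baseline.
4. **Features.** The number of accelerations and the total unsigned
   deceleration area (trapezoidal integral of |deviation|, bpm·s) —
   deceleration area is the established correlate of fetal acidemia.

The SVM uses a radial kernel with unit cost on features standardized by
training statistics (kernel width 1/d on standardized inputs); only
"nonlinear" is specified upstream, and the radial kernel is the default
nonlinear choice. k-means uses 10 seeded restarts; clusters map to
labels by training majority, ties to abnormal (the conservative clinical
direction). Both expose a continuous score (signed decision value;
centroid-distance margin) so they enter the same ROC machinery as the
deep models.

## The convolutional model

The network mirrors the compact EEG-style design: for a 2 × 1800 input,

1. a bank of `f1 = 4` temporal kernels of length `k1 = 30` (30 s at
   1 Hz — the window clinicians use to tell deceleration types apart),
   shared across the two channel rows, no bias;
2. batch normalization; then a **depthwise convolution across the
   channel pair** (multiplier `d = 2`), which is where FHR–UC timing
   relations are learned; batch norm, ELU, average pooling (4),
   dropout 0.25;
3. a **separable convolution** (depthwise length `k2 = 7`, then
   pointwise to `f2 = 8` maps); batch norm, ELU, pooling (4), dropout;
4. flatten (8 × 112 = 896 features) and a dense 2-class softmax head.

Only some of these hyperparameters are externally fixed (30-s kernels,
4–8 filters, 25% dropout, Adam with lr 10⁻³ and ε 10⁻⁵, categorical
cross-entropy, total 2130 parameters). The remaining dimensions
(`f1 = 4, d = 2, k2 = 7, f2 = 8`, pools 4 × 4) are the unique small
solution that closes the printed parameter total within the 4–8 filter
range, under two accounting conventions that the closure itself pins
down: convolutions carry **no biases** (each feeds a batch norm, whose
shift subsumes them), and each batch-norm feature contributes **4**
parameters (scale, shift, and the two moving statistics). The closed
form

```
k1·f1 + 4·f1 + 2·f1·d + 4·f1·d + k2·f1·d + f1·d·f2 + 4·f2
  + 2·(f2·⌊⌊1800/4⌋/4⌋) + 2
  = 120 + 16 + 16 + 32 + 56 + 64 + 32 + 1792 + 2 = 2130
```

is exported (`ctgnet_param_count()`) and checked against model
introspection at build time and across random configurations in the
tests.

A two-unit softmax head is used where the source describes "sigmoid …
outputs abnormality (normality = 1 − abnormality)": with two classes
and cross-entropy the two parameterizations are mathematically
interchangeable, and the softmax form matches the categorical loss.

**Implementation.** No deep-learning framework is used: forward pass,
analytic backpropagation (including full batch-norm backprop with biased
batch variance, momentum-0.99 moving statistics, ε = 10⁻³) and Adam are
implemented in vectorized base R. Activations live as `(B·T) × maps`
matrices, so batch norm is column arithmetic, temporal convolutions are
im2col matrix products or row-shifted accumulations, and pooling is a
reshape. Every gradient path is verified against central finite
differences in the test suite (relative error ~10⁻¹⁰). Training is
seed-deterministic on one thread: shuffling, dropout masks and
initialization (Glorot-uniform) all draw from R's seeded RNG.

Inputs pass through a **fixed affine transform**: (FHR − 140)/20 and
(UC − 20)/20, centering the channels at the clinical mid-band baseline
and resting tone with a common 20-unit spread. The constants are fixed,
never estimated from data, so this is a reparameterization of the raw
trace, not preprocessing in the denoising sense; it puts both channels
on comparable unit scales for the shared temporal kernels, which
materially speeds Adam's convergence at these tiny widths. Invalid
samples are linearly interpolated beforehand (the network has no mask
channel). The default schedule is minibatch 16, at most 300 epochs,
early stopping on validation loss with patience 20 and
best-weight restoration; the unstated schedule values are ordinary Keras
practice at this model size.

## The LSTM risk index

The comparison model never sees labels at its output: two identical
next-step predictors — 2 LSTM layers × 40 units, input window of 5
consecutive (FHR, UC) points, ReLU on the final hidden state, linear
2-unit head, mean-squared-error loss — are trained, one exclusively on
normal traces and one exclusively on abnormal traces. Channels are
scaled by fixed constants (FHR/200, UC/100) into ≈[0, 1]; unscaled
inputs make the gates saturate. Scoring a test trace sums the absolute
next-step errors of each model, aggregated in 5-s bins; since the bins
partition the predictions and are summed, the binned total equals the
plain error sum — the identity is asserted in the tests, and the binning
is kept because the per-bin profile is reported. The risk index is
`error_normal − error_abnormal`: positive means the abnormal-trained
model reconstructs the trace better, so the trace is called abnormal at
threshold 0, and sweeping the threshold yields the model's ROC curve.
The index is antisymmetric under swapping the two models, which the
tests check directly. The two models use different seeds (offset by a
constant) — shared initialization is not required by the method, and
independent draws avoid accidental weight cancellation in the
difference. BPTT gradients follow the standard LSTM recursions with
forget-gate bias 1; training is implemented from scratch like the CNN.

The widely quoted six-figure parameter total for such a model is not
reproducible from 2 × 40 units on 5-step, 2-channel windows by standard
counting (the true total here is ~19,900); the package does not treat it
as a target.

## Evaluation protocol

Precision, recall and F1 use abnormal-as-positive counts with the 0/0
convention "defined as 0" (reported, not hidden, when a fold degenerates
to no positive predictions). The ROC sweeps thresholds over the distinct
score values; the trapezoidal AUC over the swept staircase equals the
fraction of (abnormal, normal) score pairs ranked correctly with ties
counted half — the tests verify this against brute-force pair counting,
and the half-credit convention is exactly what the trapezoid implies
under ties.

The cross-validation protocol mirrors the source study's shape: the
abnormal cases are partitioned into 10 folds, each the test fold once;
for every fold a *fresh* equal-size normal subsample is drawn from the
eligible pool and split 9:1 alongside, so training and evaluation stay
balanced while normal controls rotate. Per-fold metrics aggregate to
mean ± SD; `repeat_with_seeds()` repeats any protocol over seeds and
formats summaries as `0.67 ± 0.03`-style strings. Because "n = 20 seeds,
t₁₉" is internally ambiguous between two-sample and paired testing,
`compare_models()` reports both variants with their degrees of freedom
printed; the benchmark commentary uses the two-sample form. Aggregation
levels (fold vs seed) are labeled explicitly in every output.

## Problem sizes and tolerances used by the checks

The bundled checks run at desk scale, chosen as the smallest sizes at
which each property is stable: the architecture and cohort closures are
exact (2130 parameters; 3681 and 162 records); generator calibration
uses one group of 162 draws against a 3-standard-error band; episode
recovery uses 15 noiseless records (~60 episodes of depth ≥ 20 bpm)
with a 0.9 recall floor at 5-s boundary tolerance; the end-to-end
benchmark trains the CNN for 40 epochs on 162 + 162 traces over three
seeds, enough for the separable defaults to converge, and compares its
mean held-out AUC (> 0.85 required) against the two-feature SVM,
asserting the deep-over-conventional *ordering* rather than any clinical
value. LSTM property tests run on short traces with small schedules
since the properties (determinism, antisymmetry, binning identity,
out-of-distribution error growth) do not depend on scale.

## Known limitations

- The simulator's class separation is optimistic; none of the reported
  synthetic metrics transfer to clinical data.
- The WFDB reader covers the format-16 dialect used by the public
  intrapartum database (one signal file, gain/baseline conversion,
  channel match by description) and nothing more.
- Episode detection assumes a locally stable baseline; traces whose
  baseline drifts faster than the 10-min median window would smear
  episode boundaries.
- Training the CNN in base R is seed-deterministic but single-threaded;
  wall-clock cost grows linearly with epochs × traces (about 2 s per
  epoch on 292 traces on a current CPU).
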