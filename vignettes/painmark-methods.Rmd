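---
title: "Methods: simulating and decoding stimulation-intensity EEG biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding stimulation-intensity EEG biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(painmark)
```

`painmark` analyses evoked 64-channel EEG recorded while transcutaneous
electrical nerve stimulation (TENS) of a residual limb elicits phantom-hand
percepts of three intensities: innocuous (INNO, 1 ms pulses at 45 Hz),
moderately intense (MOD, 5 ms at 4 Hz) and noxious (NOX, 20 ms at 20 Hz),
all at 1.6 mA. This vignette documents the model behind the synthetic data
generator, the processing and decoding choices, the numerical details, and
the limits of what the simulation can show.

## The experimental schedule

A session consists of 5 consecutive 2 s pulse trains per block, 4 blocks per
condition, presented in seeded random block order: 60 trials, 20 per
condition. Consecutive train onsets within a block are separated by the
train duration plus a delay drawn uniformly from 4 s ± 25 %. Between blocks
the generator inserts an 8 s gap rather than the minutes-long comfort breaks
of a live session: breaks carry no event-locked activity, and shortening
them only removes dead recording time from every epoch-based analysis while
keeping sessions small. A 5 s pad precedes the first train so that
pre-stimulus epochs and filter edges stay inside the recording.

## The planted signal model

Each condition's response is a sum of spatio-temporal components: a spatial
weight map times a temporal kernel. Weights fall off with squared scalp
distance from a centre channel and are zero outside the component's channel
group, giving smooth, compact topographies without a volume-conduction
model. Kernels are Gaussian bumps or plateau envelopes with raised-cosine
edges, identically zero before train onset, and the pattern repeats every
second of the 2 s train (a pulse train drives a sustained response), so both
halves of an augmented trial carry the condition signature.

Two physiological regimes are distinguished:

* **Evoked (phase-locked)** transients, identical on every trial: the early
  parietal response shared by all conditions (P2/P4/P6, 2.3 µV Gaussian at
  54 ms, sd 12 ms) and the NOX-specific central burst (Cz/C4/C6, 2.5 µV at
  700 ms, sd 45 ms — inside the 450–750 ms band where noxious activity
  concentrates).
* **Induced (non-phase-locked)** sustained oscillations, whose 11 Hz mu-band
  carrier gets a fresh random phase on every trial under a 150–1000 ms
  plateau envelope: parietal for INNO (0.5 µV) and MOD (4.5 µV),
  central for NOX (1.2 µV).

The oscillatory carrier is load-bearing, not decorative. A constant
("DC") plateau cannot represent sustained activity in this pipeline, because
the 0.5 Hz high-pass of the band-pass filter removes it almost entirely (a
4 µV constant plateau measures 0.26 µV by 650–750 ms after filtering); real
sustained responses to pulse trains ride on in-band oscillations.
An 11 Hz carrier both survives the filter and guarantees a crest inside
every 100 ms analysis window. The induced/evoked split has the standard
consequences: induced activity retains full amplitude in single-trial
max-amplitude features (so it drives decoding) but largely cancels in the
20-trial condition average (so the evoked GFP is dominated by the
phase-locked burst, and the mean post-stimulus GFP ordering
NOX > MOD > INNO follows from the planted amplitudes).

Background noise is independent per channel — pink noise (1/f power,
realised by spectrally shaping white Gaussian noise, 1.2 µV RMS) plus white
noise (1.6 µV RMS) — with an optional common-phase 60 Hz mains component
(1 µV) that exercises the notch filter. Total background is ≈ 2 µV RMS.

**Calibration.** Amplitudes were fixed once, against the measured
feature-level noise, so that the decoding task is solvable but not trivial:
after filtering, the per-channel max-amplitude feature noise is ≈ 0.85 µV
(sd) over a floor of ≈ 2 µV, giving the NOX burst a per-channel
discriminability of d′ ≈ 2.5 and the MOD-vs-INNO parietal contrast a margin
of 4 µV. Larger burst amplitudes saturate cross-validated accuracy at 1.0 on
60 trials, which erases the marginal value of individual channels;
smaller ones drop the held-out accuracy below a useful operating point.
The sustained parietal weights are concentrated at P4 (P2/P6 ≈ 0.3) while
the burst spreads broadly over Cz/C4/C6, so the parietal contrast saturates
with one channel while each central channel contributes independent
evidence.

Every planted component is recorded in a ground-truth sidecar
(group, centre channel, latency, amplitude, phase-locking), so recovery
tests compare against what was actually planted.

## Preprocessing

* **Filtering** is a fourth-order Butterworth band-pass (0.5–70 Hz) followed
  by a second-order IIR notch at 60 Hz (quality 30), both applied
  forward-backward. Zero-phase filtering is required because the analysis
  makes latency claims (54 ms, 650–750 ms); the effective order doubles.
  Numerically the cascade is evaluated in the frequency domain — forward
  plus backward application equals multiplication by the squared magnitude
  response — with 3000-sample odd-reflection padding to damp edge
  transients; this filters all 64 channels of a session in two FFTs and
  matches the time-domain filter to ~1e-5 away from the edges.
* **Epochs** are half-open windows `[t_start, t_end)` at 0-based sample
  indexing, which makes the 2 s → 2 × 1 s augmentation split exact and
  non-overlapping; the second segment keeps the trial's original pre-train
  baseline, since no later quiescent reference exists inside a train.
* **Baseline** is the per-trial, per-channel mean over [-500, 0) ms.
* **Artifact rejection** drops a trial when any channel's within-epoch
  peak-to-peak amplitude exceeds a configurable threshold (default 150 µV, a
  conventional value for high-amplitude artifact screening); the rejection
  report lists trial, worst channel and worst value, and the operation is
  idempotent.

## Features and decoding

Features are the **maximum signed amplitude** per channel in a 100 ms
window — signed, not absolute, because the topographies distinguish
enhancement from depression (an `absmax` flag provides the magnitude
variant). The window grid tiles [50, 950) ms; the ragged remainder
[950, 1000) is excluded so all windows share one width.

The **sweep** scores all five classifiers (KNN with k = 5 and Euclidean
distance; SVM; Gaussian Naive Bayes; linear and quadratic Gaussian
discriminants) on the full 64 features of the 60 original 1 s trials with
stratified 10-fold cross-validation, and picks the window with the highest
mean balanced accuracy across classifiers (ties to the earlier window). The
discriminants carry a documented ridge fallback (1e-3 of the mean diagonal)
for singular covariances, which 64 features on 54 training trials make
routine. The augmented 120-trial set is used only for PCA, the stratified
80/20 split and the held-out test, where the pipeline is: features in the
best window → PCA to 2 components fitted on training rows only → SVM with
hyperparameters grid-searched ({linear, RBF} × cost {0.1, 1, 10, 100} ×
kernel width {scale heuristic, 0.01, 0.1, 1}, one-vs-one for three classes)
by 10-fold cross-validation on the training scores → one evaluation on the
untouched 20 %. Corrupting test rows provably changes nothing fitted.

**Sequential forward selection** greedily adds the channel that most
improves classification of the best-window features. Scoring uses
leave-one-out cross-validation with pooled predictions and a KNN scorer:
on 60 trials the marginal gain of one channel is one or two correctly
recovered trials, which fold-assignment noise in a k-fold score would
swamp, while the leave-one-out score has no fold randomness; KNN penalises
irrelevant candidates naturally because they dilute the distance metric.
Ties break to the lower channel index.

## Statistics

Global field power is computed as the spatial standard deviation across
electrodes at each time point — the standard reference-free field-strength
measure, invariant to a common offset and |c|-equivariant under scaling.
Peak detection returns the extremal channel/latency/amplitude over a
spatio-temporal slab with deterministic ties (earliest latency, then lowest
channel index). The nonparametric battery mirrors common ERP practice:
one-sample Kolmogorov–Smirnov against the standard normal on the
standardised sample (the classical KS null, without a Lilliefors
correction), Mann–Whitney U with midrank ties and continuity-corrected
normal p, Kruskal–Wallis with tie correction, and a Tukey HSD post hoc
applied to rank-transformed pooled data so the omnibus test and the post
hoc share a scale (`on_ranks = FALSE` gives plain Tukey on raw values). One
caveat is asserted in the tests: with a far-shifted group, the rank
transform compresses that group's variance and can make the remaining null
pair look more significant than raw-scale Tukey does; the raw variant is
preferable when groups are wildly separated. The pipeline's omnibus
comparison uses, per condition, the per-trial best-window maximum at the
noxious peak channel, plus a matched pre-stimulus "background" sample.

## Problem sizes and determinism

A single master seed fans out to every stage through a fixed counter scheme
(`seed + 7919 · stage`), so any stage can be re-run in isolation and a full
pipeline run is byte-reproducible. The test suite exercises the complete
60-trial study over 20 generator seeds (about five minutes on one CPU) and
uses reduced 30-trial sessions for the end-to-end determinism checks;
statistical nulls use 1000 replicates (Kruskal–Wallis type-I error) and
10 000 draws (schedule jitter, permutation chance level).

## Known limitations

* The generator emulates event-locked structure, stationary 1/f background
  and mains interference — not eye blinks, muscle bursts, electrode drift,
  trial-to-trial latency jitter or habituation. Passing recovery tests shows
  the pipeline recovers what the model plants; it does not certify
  performance on artifact-laden patient data, where the rejection and
  filtering stages carry more weight.
* Spatial structure is a distance falloff on the unit disc, not a
  biophysical forward model; topographic claims are therefore qualitative
  (which channel group peaks), not quantitative maps. Source localisation is
  out of scope.
* With 60 trials, the greedy selection of *redundant* channels is
  fundamentally noise-limited: once two informative channels are picked, a
  third, partially redundant one improves the score by at most one or two
  trials, which is the same magnitude as the maximum score fluctuation over
  the ~60 irrelevant candidates; exact ties resolve to the lowest channel
  index. Selection of a full redundant group is therefore not a stable
  event at this sample size under any calibration that keeps the task
  non-trivial — the constructed-data recovery test (graded class contrast on
  the central group, 120 trials, reduced candidate pool) demonstrates the
  regime where greedy selection is reliable.
* The paper-scale effect — whether these particular latencies and channel
  groups generalise beyond a single participant — is outside what any
  simulation can address.
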