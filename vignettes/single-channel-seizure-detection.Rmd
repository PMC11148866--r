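---
title: "Patient-specific single-channel seizure detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific single-channel seizure detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monoseize)
```

## The problem

Long-term EEG monitoring for refractory epilepsy is limited in daily life by
the full 18-derivation scalp montage. If a neurologist can designate the one
bipolar derivation that carries a patient's most distinctive seizure activity
— among four wearable-friendly candidates on the forehead (Fp1-F3, Fp2-F4)
and behind the ears (P7-O1, P8-O2) — then a patient-specific detector trained
on that single channel can approach the performance of a full-montage
detector. `monoseize` implements that pipeline end to end: channel reduction
(18 → 4 → 1), windowed ictal/interictal classification, and event-level
detection on continuous recordings, together with a synthetic-EEG generator
so every stage is testable without access to clinical data.

## Signal path and conventions

Recordings are matrices of N channels × T samples in microvolts at 256 Hz.
Referential inputs are re-referenced to longitudinal bipolar derivations
(anode minus cathode); already-bipolar files are passed through unchanged.
Times are seconds from file start; intervals are half-open `[onset, offset)`;
the sample of time *t* is `floor(t * fs)`. Everything downstream — labeling,
event extents, overlap matching — uses this one convention.

Signals are band-passed 1–30 Hz (4th-order Butterworth, applied
forward–backward). The realization is a package choice: zero-phase filtering
keeps filtered seizure morphology aligned with the annotated onsets, which
matters because onset latency is a reported metric. No artifact rejection is
performed; a hook exists but defaults to pass-through, since rejecting
artifacts would silently change the class composition of the training data.

Windows are 4 s (1024 samples). A window is labeled *ictal* only if it lies
entirely inside an annotated seizure and *interictal* only if it overlaps
none; boundary-straddling windows are excluded and counted, because a window
that is half seizure has no honest binary label. The training step size is
configurable: a 1-sample step (3.996 s overlap between consecutive windows)
maximizes the number of training segments at clinical scale, while the
desk-scale default is 256 samples (1 s). Event-level inference always uses
4-s windows at a 1-s step.

Because ictal time is rare (tens of minutes against tens of hours), training
draws class-balanced batches: each batch holds equal numbers of ictal and
interictal windows, the majority class cycling without replacement and the
minority class recycling with reshuffles. This is the balancing *goal*
stated by the protocol; the concrete sampling scheme is ours.

## The classifier

The binary classifier is a parallel two-branch 2-D convolutional network on
the raw N × 1024 window. Kernels span one electrode row and 3 (branch A) or
5 (branch B) time samples, so convolutions never mix channels; channels are
combined only by global average pooling and the dense head. Each branch
stacks three blocks of convolution (32, 64, 128 filters; strides 2, 2, 1;
"same" padding) → batch normalization → rectifier → max-pooling (size 3,
stride 3, no padding). For a 1024-sample window the temporal lengths are
512 → 170 → 85 → 28 → 28 → 9 per branch. The two 128-feature branch outputs
are globally average-pooled, concatenated (256 features), passed through a
64-unit rectified dense layer and a 2-way softmax whose second entry is the
ictal probability; a window is called ictal iff that probability is ≥ 0.5
(ties classed ictal, favoring sensitivity). Training minimizes binary
cross-entropy with RMSprop at learning rate 3 × 10⁻⁴ and stops early when
validation loss has not improved for 15 epochs, restoring the
best-validation weights.

Several architectural details are deliberate package choices where the
design was open: the dense head is the smallest one consistent with "fully
connected layers" (64 units then softmax, configurable); both branches share
the same stride triple; batch normalization sits between convolution and
activation; max-pooling truncates a remainder shorter than the pool. The
batch-norm running-average momentum defaults to 0.9 so that inference
statistics track batch statistics within the short training schedules used
here (hundreds of batches rather than hundreds of thousands); it is
configurable. All layers are implemented in compiled code (im2col + BLAS
matrix products) with an R-level numerical-differentiation check in the test
suite.

## From probabilities to events

Sliding 4-s/1-s classification of a continuous recording yields one ictal
probability per second. Three post-processing steps turn the trace into
events:

1. **Smoothing** by a Savitzky–Golay filter with window length 10 and
   polynomial order 3. An even window is unusual; rather than silently
   substituting 11, the implementation is a general local least-squares fit
   supporting even windows (5 samples left of the point, 4 right), truncated
   windows at the edges, and output clipped to [0, 1]. Odd windows work too.
2. **Thresholding and run length**: steps with probability strictly
   exceeding *Th* are candidates, and a maximal run of at least *L*
   consecutive candidates becomes an event covering
   `[first window start, last window start + 4 s)`.
3. **Merging**: events whose gap is less than 10 s are merged, transitively.

An annotated seizure overlapped by any detected event is *correct* (latency
= earliest overlapping detected onset minus annotated onset, possibly
negative — detections may precede the annotated electrographic onset and are
reported signed); an unoverlapped annotation is *missed*; a detected event
overlapping no annotation is a *false alarm* (one event spanning two
seizures credits both and is no false alarm). Event sensitivity is
correct / annotated (defined as 100 % for a recording with nothing to miss),
FAR is false alarms per hour of the scored recording, and latency is
averaged over correct detections.

*Th* (grid 0.2–0.9 by 0.1) and *L* (5–10) are tuned per case by maximizing
pooled event sensitivity on the *training* files' continuous traces, ties
broken by minimal FAR, then larger *L*, then larger *Th* — the most
conservative of the equally sensitive settings. Whether the reference
protocol tuned on held-out data is not determinable from its description; we
use the leakage-free reading. The Savitzky–Golay parameters stay fixed at
(10, 3) by default.

## Evaluation protocol

Evaluation is patient-specific and file-wise: *k* equals the number of files
with at least one seizure; each such file is the event-level test file of
exactly one fold. Training data for a fold gathers ictal segments from the
other *k* − 1 seizure files and interictal segments from all seizure-free
files, split 7:2:1 into train/validation/test for the segment-level
evaluation (sensitivity, specificity, accuracy, and rank-based AUC with
midrank ties). Per-case results aggregate folds as mean ± sample SD (n − 1).

The 7:2:1 split granularity is the one genuinely consequential open choice.
With overlapping windows, a random segment-level split leaks near-duplicate
windows between train and test, inflating segment metrics. The default is
therefore *grouped contiguous-block* splitting: each (file, class) group is
cut into three contiguous time blocks, and the few later-part segments still
time-overlapping an earlier part are dropped (grouping by class is safe
because an ictal and an interictal window of one file can never overlap in
time once straddlers are excluded). A `random_segments` mode reproduces the
literal random reading. When a test block ends up single-class — possible
for files with few, short seizures — segment metrics for that fold are
reported as `NA` and flagged (`seg_metrics_ok`), never silently dropped;
event-level scoring is unaffected.

## The synthetic-EEG generator

The generator emulates the *structure* of a monitored pediatric case, not
its biophysics: per-electrode 1/f background noise (default exponent 1, RMS
20 µV), optional mains line, and seizures as amplitude-ramped rhythmic
bursts (default 3–7 Hz, inside the analysis band) with a slow ±15 %
frequency drift, 30–90 s long, at least 60 s apart, with margins at file
edges. Burst gains are placed antisymmetrically on the electrode pairs of
the four wearable derivations: the dominant pair receives ±1/2, the other
three pairs ±attenuation/2 (default 0.2). After montage derivation the
dominant channel carries the full burst and the other wearable channels
exactly the attenuation fraction; full-montage derivations sharing an
electrode with an injected pair pick up a partial projection, as focal
discharges spread on real scalp recordings. `snr_ictal` (default 5) is
defined against the *derived* channel background, whose RMS is √2 times the
electrode RMS because a bipolar derivation differences two independent noise
processes.

The desk-scale defaults — 4 files of 0.25 h, 2 with seizures — deliberately
sit below the clinical regime of several 1–4 h files; full-scale generation
is configuration only. What passing tests on this material show is that the
pipeline's machinery is correct and that a band-limited, spatially localized,
honestly annotated discharge is recovered on the designated channel with low
false-alarm rates. What they cannot show is robustness to real artifacts
(blinks, EMG, electrode pops), inter-patient morphology variation, or
annotation noise — none of which the generator models.

## Problem sizes and numerical choices

The bundled experiments and tests use the desk-scale study configuration:
training windows at a 256-sample step, balanced batches of 16, 20 batches
per epoch, at most 10 epochs. These sizes were chosen once as the package's
desk-scale conditions; at clinical scale one would raise them toward the
reference settings (1-sample step, early stopping over many tens of epochs)
by configuration alone. Other numerical choices: Glorot-uniform
initialization; RMSprop decay 0.9 with stabilizer 10⁻⁷; batch-norm ε 10⁻³;
probabilities clipped at 10⁻¹² inside the cross-entropy; EDF samples
quantized to 16 bits over a symmetric per-channel physical range (error at
most one digital step); all randomness flows through explicit seeds, and
identical seeds give bitwise-identical generated signals, batch sequences
and trained parameters.

## Known limitations

- The headline clinical numbers of the reference protocol require the full
  clinical dataset, neurologists' re-annotations, and GPU-scale training;
  the package reproduces the method and its in-protocol arithmetic, plus
  property-based recovery on synthetic cases.
- Patient-independent (cross-patient) detection is out of scope, as are
  alternative architectures and adaptive post-processing.
- The EDF codec reads plain continuous 16-bit EDF; EDF+ annotation channels
  and discontinuous files are not supported.
- With very short or very few seizures per file, the leakage-free grouped
  split can exhaust a class in the smallest part; such folds flag their
  segment metrics as `NA` rather than reporting on a degenerate split.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- synth_config(seed = 1)              # 4 files, 0.25 h, 2 with seizures
case <- generate_case(cfg)
res <- run_case(case$recordings, case$annotations,
                channel_policy("single",
                               single_channel = case$ground_truth_channel),
                model_cfg = model_config(seed = 2, max_epochs = 10,
                                         epoch_batches = 20, batch_size = 16))
res$summary
```

The README shows the output of this run; `scripts/acceptance.R` recomputes
the same quantities from scratch under a caller-supplied seed.
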