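---
title: "Continuous pain-intensity monitoring: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous pain-intensity monitoring: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painmonitor)
```

`painmonitor` estimates pain intensity continuously — once per second — from
two modalities of a 25 Hz multichannel recording: electrodermal activity
(EDA, one skin-conductance channel) and facial activity (21 channels: three
head-pose angles and 18 action-unit tracks). This vignette explains the
generative model behind the synthetic sessions, the descriptor and dataset
conventions, the predictive models, and the places where a genuinely open
design choice was made.

## The monitoring problem

Subjects experience two stimulus qualities (heat, electrical) at three
calibrated intensities (low, moderate, severe), in two temporal forms:
phasic stimuli of 5 s repeated 30 times per (quality, intensity) with
pauses of 8–12 s, and tonic stimuli of 60 s applied once per pair with
5-minute pauses — roughly 80 minutes of recording per subject, most of it
no-pain baseline. The system must output, for every second, either a class
(no pain, or quality × intensity) or a continuous intensity in [0, 1]
(baseline 0, low 1/3, moderate 2/3, severe 1).

## The synthetic-session generator

Real pain databases with this protocol are access-restricted, so the
package treats the generator as a first-class, tested module: it defines
the conditions under which every downstream claim is verified.

**Schedule.** All 180 phasic events are laid out in one randomized block
(pauses uniform on 8–12 s), followed by the six tonic events in randomized
order (fixed 300 s pauses). The true interleaving of phasic and tonic
phases in the laboratory protocol is not public; the block order is a
configuration option (`block_order`) rather than a guess, and nothing
downstream depends on it because dataset filters key on label codes. A 10 s
baseline lead-in and tail bracket the session so that warm-up and trailing
windows exist.

**EDA.** The channel is a sum of a tonic level (baseline 1–4 µS with a slow
sinusoidal drift of 0.1–0.5 µS over ~15 min), one stimulus-locked
skin-conductance response per event, and i.i.d. Gaussian noise (sd 0.05 µS
by default). The response kernel is the standard difference of two
exponentials (rise 0.75 s, decay 4 s, peak-normalized; peak offset
`scr_kernel_peak_time()` ≈ 1.55 s), delayed by a per-subject latency drawn
from [1, 3] s. Phasic events contribute a transient with peak amplitude
`eda_gain × intensity × (1 + 10 % jitter)`; tonic events contribute a
sustained plateau built from the kernel's normalized integral. Subject
gains are log-normal around 0.3 µS per intensity unit — the order of
magnitude of event-related skin-conductance responses.

**Facial activity.** Eight of the 21 channels are designated
pain-responsive (standing in for the brow-lowering / orbit-tightening /
levator action units that encode pain); they receive stimulus-locked bumps
(rise 0.5 s, decay 1.5 s; plateau for tonic events) with amplitude
`facial_gain × intensity` and fixed per-channel weights, delayed ~2 s, the
behavioural lag the label shift later compensates. `facial_gain` is
`0.4 × (category − 1)` for the subject's expressiveness category 1–4, so
category-1 subjects show no facial response at all — the situation that
motivates both the sample-weighting method and multimodal fusion. All other
channels are pure noise.

**Artifacts and splits.** A configurable fraction (2 % by default) of
samples has labels overwritten with the artifact codes −10/−11 in
non-overlapping 1–3 s spans (signals untouched — only the labelling is
invalid, as with false starts or stimulus overlaps). Subjects are assigned
to the four expressiveness categories round-robin and split 80/10/10 at the
subject level, stratified by category as far as the split sizes allow;
every split automatically contains all intensities because every subject
receives the full protocol.

**What the generator does not emulate:** habituation and sensitization
across repetitions, autocorrelated sensor noise, motion artifacts in the
signal itself, spontaneous (non-stimulus) skin-conductance responses, and
inter-channel correlation structure of real action units. Tests passing on
synthetic cohorts therefore demonstrate that the pipeline recovers a known
stimulus-locked signal under realistic timing, imbalance and
between-subject variation — not that any particular performance level
transfers to real recordings.

## Descriptors, standardization, windows

Each channel is summarized once per second by four statistics — minimum,
maximum, mean, and population standard deviation (ddof 0; the convention is
stated because it is not observable from the 25-sample segments) — of the
raw series and of its first and second finite differences: 12 features per
channel, hence 12 for EDA-D and 252 for FAD. Derivatives are computed once
over the full series and segmented by the left index of each difference, so
the last second of a session has 24 first-difference samples; an
alternative (per-second derivative recomputation) would differ only at
segment boundaries.

Features are z-scored within subject over the subject's entire recording
(zero-variance features map to 0). Subjects never straddle splits, so this
cannot leak information across splits; whether the within-subject
statistics should be restricted to a training period is an open question in
any deployment scenario — here the full-recording convention is used and
stated.

Labels are shifted 3 s forward (responses lag stimuli by 2–3 s), collapsed
to one label per second by majority vote over the 25 samples (ties break
toward artifact codes first, then higher intensity), and windows of 10
consecutive per-second frames predict the label of the following second:
inputs are 10 × 12 or 10 × 252, one window per second from t = 10 on, so a
T-second session yields T − 10 windows. Seconds are indexed from 0 and
windows are half-open `[t − 10, t)`.

## The 11 datasets and the reduction rule

Each dataset keeps one stimulus type and optionally one quality; artifact
windows are dropped, and each baseline run is attributed to the
*immediately following* pain sequence — baseline attached to excluded
sequences is dropped, as is the trailing baseline. Windows are the atomic
"samples": filters act on a window's label second, not on its 10-s feature
history, so a window whose history touches excluded material is kept if its
label second is kept.

The reduced variants keep, for each pain sequence of `m` windows, only the
`m` immediately preceding no-pain windows. When every sequence has at least
`m` preceding baseline windows this gives exactly 50 % no-pain; shorter
runs (e.g. a lead-in mostly consumed by the 10-s warm-up) keep everything
they have, which is why observed fractions sit marginally below 50 %. The
same per-sequence rule is applied to the tonic datasets; a different
resulting fraction there is a property of the data mix, not a different
rule. There is no reduced heat tonic dataset: heat tonic data is already
close to balanced (the 60 s stimuli outweigh their attributed pauses).

Class encodings: 7-class datasets order (BL, heat 1–3, electrical 1–3),
4-class datasets (BL, 1–3). The continuous target is `intensity / 3`
regardless of quality — both qualities at intensity 2 map to 2/3. This is
also the scale on which classification predictions are evaluated with MSE
and ICC, via the predicted class's intensity.

## Models

**Random forests** (via `ranger`): 100 trees, maximum depth 10, probability
forests for classification; windows are flattened to 120- or 2520-vectors
(the forest has no native notion of time). Single-threaded with a fixed
seed for bit-reproducibility.

**Recurrent models.** Six small architectures: one LSTM layer (4 units for
A/C, 8 for B/D, ReLU cell activation), the per-step outputs flattened and
passed through a ReLU dense layer (128 for A/C, 64 for B/D) into the head —
softmax over 7 (A) or 4 (C) classes with categorical cross-entropy, or one
sigmoid unit with binary cross-entropy for regression. `C(r)`/`D(r)` are
the 4-class-dataset aliases of the `A(r)`/`B(r)` shapes. The implementation
is self-contained batched matrix code with backpropagation through time and
Adam, and is verified against central finite differences in the test suite
(relative error < 1e-4 on every parameter tensor); seeded runs are exactly
reproducible.

The reference training budget is 2000 epochs at learning rates 1e-4, 1e-5
or 1e-6 with batch size 512. For desk-scale work (tests, the smoke
pipeline) the package uses a reduced profile — tens of epochs at the
conventional Adam rate 1e-3 — which converges on the strongly-informative
synthetic cohorts; the profile is a deliberate scale choice, not a claim
about the reference setting.

**Sample weighting.** A facial-feature RF classifier scores the training
windows; every window whose score *for its own true class* exceeds 0.3 is
duplicated once (appended in stable order). The threshold is applied to the
true-class score rather than the maximum score — the method's purpose is to
up-weight windows with a clear facial response to their actual label; the
max-score reading would also duplicate confidently *mis*classified
windows. The augmented index vector is applied to the training windows of
whichever modality is then trained (LSTM-SW variants).

**Fusion.** Decision-level, fixed mean-score mapping: per-class scores (or
regression outputs) of the EDA and facial models are averaged with equal
weights; the fused class is the argmax with ties to the lowest index. Equal
weights are part of the method definition — there is nothing to tune — and
fusion is only applied within a method family.

**Trivial baseline.** Always predicts no pain (score 1 on baseline;
constant 0 for regression). Under the pain-class-pooled micro F1 it scores
exactly 0, and under ICC(3,1) a constant rater scores exactly 0 — useful
anchors for both metric implementations.

## Evaluation conventions

Micro-averaged F1 pools true/false positives and false negatives over the
*pain* classes only; baseline is excluded from the pooling (a baseline
prediction on a pain window is a pooled false negative, a pain prediction
on a baseline window a pooled false positive). Pooling over all classes
would instead award the trivial predictor the baseline prevalence, which
contradicts its role as a zero anchor.

ICC(3,1) is the two-way mixed-effects, consistency, single-rater
coefficient with k = 2 raters (prediction, ground truth), computed from the
ANOVA decomposition `(MSR − MSE) / (MSR + MSE)` with windows as rows. It is
invariant to adding a constant to either rater, equals 1 for `y = x + c`,
and is pooled over the test split's subjects (one number per dataset)
rather than averaged per subject. For classification models, MSE and ICC
are computed after mapping the predicted class to `intensity / 3` — i.e. on
the same normalized scale as regression — rather than on raw class indices,
which would conflate quality with intensity in the 7-class datasets.

Degenerate cases are explicit: ICC of two constant vectors is undefined
(`NA` with a warning); zero-variance features standardize to 0; empty
window sets propagate as empty prediction sets, not errors.

## Problem sizes and reproducibility

The test suite builds everything it needs in code: tiny hand-checkable
streams for the filter/reduction rules, 60-s random inputs for the
descriptor oracle (direct-loop recomputation, agreement ≤ 1e-10), and a
10-subject cohort under the full stimulation protocol for the end-to-end
parameter-recovery check, where an EDA-D LSTM regressor on the reduced
phasic dataset reaches ICC ≥ 0.5 against held-out subjects and beats the
trivial baseline (with the reduced training profile: 40 epochs, lr 1e-3).
These sizes keep the whole suite within a few minutes on one CPU while
leaving the recovery margin wide. All randomness flows through explicit
seeds; cohort generation, forests and recurrent training are reproducible
run-to-run.

## Known limitations

- The generator's facial channels are independent noise outside the
  responsive subset; real action units co-move and include blinks and
  speech.
- No habituation: response amplitude is stationary across the 30
  repetitions.
- The LSTM implementation is plain R; it is sized for these small
  architectures (4–8 units, ≤ 2520 inputs) and desk-scale epochs, not for
  large-scale training.
- Person standardization uses the full recording (see above); deployments
  that stream data would need running statistics.
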