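---
title: "Unsupervised per-channel segmentation of EEG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised per-channel segmentation of EEG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegseg)
```

## The problem and the model

Clinical electroencephalography produces hours of multichannel voltage
traces in which the events of diagnostic interest — epileptiform
discharges — occupy a fraction of a percent of the recorded time. `eegseg`
labels each channel of a recording, fully unsupervised, with a small set of
discrete activity states so that a reviewer can jump straight to the rare
non-background stretches. Nothing is learned across patients: every
recording, and every channel within it, is modelled from scratch, which
makes the method indifferent to montage, electrode count, and inter-patient
variability.

The pipeline has three stages, applied independently per channel:

1. **Spectral featurization.** The channel is cut into overlapping windows
   of 256 samples (one second at the 256 Hz reference rate) stepping by 192
   samples, and each window is mapped to the modulus of its full 256-point
   discrete Fourier transform. The full conjugate-symmetric spectrum is
   kept, rather than the 129-bin one-sided one, because the autoencoder's
   architecture fixes the input width at 256 — matching the published
   description of a 64-unit hidden layer as "a quarter of the input".
   No taper is applied by default (a Hann taper is available in
   `frame_config()`), and magnitudes are used raw: the downstream stages
   are covariant to an overall rescaling of the input.

2. **Per-channel autoencoder.** A single-layer encoder and single-layer
   decoder with a 64-unit bottleneck and leaky-rectifier activation
   (negative slope 0.01, hidden layer only; linear output) are trained on
   the channel's frames with mean-squared loss, learning rate 0.001, 25
   epochs. The bottleneck forces the network to encode the channel's
   *dominant* spectral repertoire; frames it cannot reconstruct are, by
   construction, rare or unusual. The per-frame anomaly signal is the
   element-wise absolute difference between the frame and its
   reconstruction (squared error for training, absolute error for output —
   the conventional split).

3. **Penalized-Viterbi segmentation with a generative hypothesis loop.**
   The sequence of 256-dimensional error vectors is segmented by a hidden
   Markov model whose states are centroids in error space. The exact
   dynamic program minimizes the total emission cost plus a fixed penalty
   (default 200) per state transition, which yields piecewise-constant
   segmentations. States are *hypothesized*: starting from a single state
   at the global centroid, the loop repeatedly (a) re-estimates centroids
   from the current segmentation, (b) proposes a new state from the
   worst-fitting contiguous window of frames, and (c) accepts the proposal
   only if it lowers the total path cost and the new state claims at least
   `min_frequency` (default 20) frames; under-supported states are dropped
   and their frames reassigned. The most frequent state is declared the
   background; all other states are candidate anomalies (an alternative
   policy flags only states whose mean error exceeds the background's by a
   configurable factor).

## Numerical and design choices

Several details of the original description are open; the package's
choices, and why:

* **Emission cost and the meaning of the penalty.** The emission cost of
  frame $x_t$ under state $k$ is $\lVert x_t - c_k\rVert^2 / (2\hat\sigma^2)$,
  where $\hat\sigma^2$ is the robust per-dimension variance of the
  sequence, estimated once as $\mathrm{median}_t\,\lVert x_t - \bar
  x\rVert^2 / d$ (the median keeps rare high-amplitude frames from
  inflating the estimate). This is the negative log-likelihood of an
  isotropic unit Gaussian after standardization, so a typical background
  frame costs about $d/2$ and the transition penalty of 200 has a stable,
  unit-free meaning: a contiguous stretch of frames a few standard
  deviations off background pays for its two transitions within a handful
  of frames, while temporally scattered variance — however large — cannot,
  because every isolated excursion would incur its own penalties. A
  mean-over-dimensions emission (per-frame cost near 1) was considered and
  rejected: it makes a penalty of 200 unpayable by any realistic event.

* **State proposal.** "The worst-fitting contiguous segment" is read as
  the sliding window of `min_frequency` consecutive frames with the
  highest mean emission cost under the current segmentation. A run-of-the-
  current-path reading cannot bootstrap: with one state the whole sequence
  is a single run whose centroid is the existing state. Tying the window
  length to the pruning threshold means proposals are never created just
  to be pruned.

* **Tie-breaking.** Among cost-equal Viterbi paths the lexicographically
  smallest (lower state ids first) is returned, via a backward dynamic
  program and a greedy forward reconstruction; segmentation is therefore
  bit-reproducible across platforms.

* **Optimizer.** The training recipe fixes the learning rate (0.001) and
  epochs (25) but not the optimizer or batching. Plain full-batch gradient
  descent takes only 25 vanishingly small steps under that recipe and
  leaves the network at its random initialization, so the package defaults
  to Adam with minibatches of 16 consecutive frames — 0.001 is Adam's
  canonical rate, and at a few hundred frames per channel this converges
  well within 25 epochs. Both plain gradient descent and full-batch
  updates remain available in `ae_config()`. Batches are consecutive row
  blocks with no shuffling, keeping training deterministic given the
  initialization seed.

* **Input normalization.** Frames are scaled by the channel's peak
  magnitude before training (recorded in the model; errors are reported on
  the original scale). Raw FFT magnitudes of microvolt signals put the
  mean-squared loss in a numerically unhelpful regime; scaling is a
  stability measure, not a modelling choice, and can be disabled.

* **Weight initialization** is uniform in
  $\pm\sqrt{6/(\text{fan}_{in}+\text{fan}_{out})}$ under a per-channel
  seed (`seed + channel - 1`), so channels are decoupled yet the whole fit
  is reproducible and independent of execution order and worker count.

* **Degenerate inputs.** A signal shorter than one window yields zero
  frames with a warning; an all-zero channel trains at exactly zero loss;
  a sequence shorter than `min_frequency` keeps a single state (the
  support invariant is vacuous there); metrics with zero denominators are
  reported as undefined (`NA`), never silently as 0.

## What the synthetic generator emulates — and what it does not

`synth_eeg()` produces multichannel recordings of alpha (8–12 Hz) plus
theta (4–7 Hz) sinusoids with Gaussian noise, and superimposes rare
spike-wave discharge events: a ~3 Hz slow wave with a sharp Gaussian
transient per cycle, ramped on and off over a second, with RMS amplitude a
configurable multiple (default 4) of the background RMS — mid-range for
ictal rhythms, which typically run several-fold above background. Default
fixtures are 8 channels for 10 minutes with 3 events of 10–60 s; event
time is capped at 20% of the recording, a deliberately *harder* rarity
regime than clinical practice (well under 1%), because at desk scale an
autoencoder sees anomalous frames often enough to start encoding them.
Event start times and durations are whole seconds so the written
annotation summary round-trips exactly.

The generator does **not** emulate: volume conduction or any dipole
physics, inter-channel correlation structure, artifacts (blinks, EMG,
electrode pops), nonstationary background (sleep stages, drowsiness), or
montage-specific polarity. Passing the end-to-end tests therefore shows
that the mechanism — rare, spectrally distinct, temporally contiguous
events versus a stationary background — is detected reliably; it does not
show clinical-grade performance on real EEG, where background
nonstationarity will legitimately produce additional non-background states
and lower frame-level specificity.

## Problem sizes used by the test suite

The packaged checks run at desk scale: exhaustive-search verification of
the Viterbi decoder on 500 instances of up to 8 frames and 3 states;
planted-segmentation recovery on 100 sequences of three 60-frame regimes
in 32 dimensions; autoencoder contrast on 400 background frames from a
rank-48 subspace of 256 dimensions against orthogonal-subspace frames,
over 10 seeds; and end-to-end detection on 20 default fixtures (60 planted
events). These sizes were chosen so the entire suite completes in minutes
on one CPU while each property is still measured, not merely smoke-tested.

## A worked example

```{r example}
synth <- synth_eeg(synth_config(seed = 11))
fit <- eeg_segment(synth$recording)
summary(fit)
ev <- evaluate_segmentation(fit, synth$annotations)
ev$event_capture$captured
round(ev$metrics$specificity, 3)
```

Each channel typically resolves 2–4 states: one background state claiming
the vast majority of frames and one or more discharge states covering the
planted events, which is exactly the reviewer-facing output: a handful of
flagged intervals per channel.

## Known limitations

* Per-frame sensitivity is a lower bound on practical sensitivity: events
  only partially overlap fixed windows, and the frame-truth rule counts a
  frame positive on a single sample of overlap.
* One autoencoder per channel per recording means model quality degrades
  on very short recordings (few frames); pooling channels
  (`pool_channels = TRUE`) is the supported fallback.
* The HMM has no learned covariances and no probabilistic decoding —
  emissions are isotropic distances by design, keeping the method
  desk-scale and deterministic.
* EDF support covers the classic 16-bit format; EDF+ embedded annotations
  and BDF are out of scope.
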