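---
title: "Gaussian-mixture spatial patterns for high-density surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-mixture spatial patterns for high-density surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgrid)
```

## The problem and the model

A high-density surface-EMG grid measures muscle activity at many nearby
skin sites simultaneously. During a static contraction, different motions
recruit different portions of the muscle group under the grid, so the
*spatial distribution* of amplitude across channels — not any single
channel's envelope — carries the motion information. `semgrid` implements
a deliberately simple and interpretable representation of that
distribution:

1. per-channel RMS amplitude in sliding windows,
2. a single one-dimensional Gaussian mixture fitted to the **pooled**
   amplitudes of all channels,
3. each channel's amplitude replaced by the index of its
   maximum-posterior mixture component, arranged on the electrode grid.

The result, a grid of small integers ("simplified 2D spatial pattern"),
discretizes amplitude into data-driven activation levels that are shared
across channels — channel 3 at level 7 means the same thing as channel 12
at level 7. That shared scale is what makes the patterns comparable across
channels, time, and (after refitting) sessions, and it is why the mixture
is pooled rather than fitted per channel. A small feed-forward network
then maps patterns to motion classes and a causal majority vote smooths
the decision stream.

## Windowing and features

Windows are 200 ms long and slide every 5 ms; both must convert to whole
sample counts at the record's sampling rate (1 kHz by default). Windows
anchor at the record start and a ragged final window is discarded, so a
record of $n$ samples yields $\lfloor (n-W)/S \rfloor + 1$ windows. RMS is
computed from prefix sums of squares, making the batch extractor $O(n)$;
a streaming extractor emits each window as its last sample arrives and
agrees with the batch result to better than $10^{-9}$ relative.

Each window optionally takes the modal per-sample motion label (ties go to
the earlier class in the declared order) — needed for supervised training;
windows that straddle a transition have no single correct label, which is
why evaluation distinguishes *steady-state* windows (further than 0.3 s
from any transition: one window length plus the onset ramp).

A centered moving average (default span 41 windows ≈ 205 ms at the 5 ms
step, shrunken at the edges) is available for display-quality envelopes.
It is **off** by default before mixture training: smoothing changes the
amplitude distribution, and the pipeline treats it as a presentation
choice, exposed as an option.

## Filtering

The acquisition chain is modeled digitally: an order-4 Butterworth
bandpass at 5–450 Hz (flat passband, the standard sEMG band at 1 kHz
sampling) and a biquad notch (RBJ cookbook form) at the mains frequency,
default 60 Hz with quality factor 30 (3-dB width 2 Hz), configurable to
50 Hz. Offline filtering is forward–backward (zero phase); a causal
single-pass mode mirrors a real-time system and is documented as
non-identical (group delay, startup transient flagged as warm-up).
`frequency_response()` exposes the designed transfer function; at these
defaults the single-pass gain is 0 dB at 100 Hz, −56 dB at 1 Hz, −265 dB
at the notch center and −0.002 dB an octave above it.

## The mixture fit

EM on the pooled 1D sample is written out directly (E-step in log space
with log-sum-exp; weighted M-step). Numerical choices:

* **Initialization** is deterministic: means at the $(2i-1)/2K$ quantiles,
  variances at the pooled variance, uniform weights. Quantile
  initialization is robust in 1D; an optional seeded random-restart mode
  (means drawn from the data, best final likelihood wins) covers
  pathological starts.
* **Variance floor** $10^{-6}\times$ pooled variance prevents singular
  collapse; the fit records whether it was ever active.
* **Convergence**: relative log-likelihood improvement below $10^{-8}$ or
  500 iterations. On long sessions with many near-identical low-amplitude
  windows EM can crawl near a ridge and stop at the iteration cap; the
  fitted density and, more importantly, the induced discretization
  boundaries are stable well before that, so the cap is operationally
  harmless and the `converged` flag reports it honestly.
* **Labeling**: components are sorted by ascending mean after fitting, so
  cluster index 0 is always "quietest". Assignment is hard argmax of the
  posterior (ties to the lower index) — a deterministic index, monotone in
  amplitude for equal-variance components.
* **Degenerate data**: an all-identical sample with $K>1$ collapses to one
  component with a warning flag; $1 < \text{distinct} < K$ is an error.

`K = 10` is the classification default; `K = 5` suits visual exploration;
already `K = 2` separates distinct motions on well-separated data (a
property the test suite checks). A pooled session of $\sim$16 000 windows
× 16 channels is large, and consecutive 5 ms-step windows overlap 97.5 %,
so `run_pipeline()` fits on every 4th window (`fit_stride = 4`) and
discretizes all windows; `fit_gmm()` itself defaults to using everything.

The test suite validates the EM against `mclust`'s univariate EM from
identical initializations (final log-likelihood within $10^{-4}$) and
against known generative parameters; `mclust` is never used in the
implementation itself.

## Channel selection

Channels are ranked by the empirical mutual information (bits) between
their cluster index and the class label. The score is 0 for a channel
whose index never varies and reaches $H(\text{label})$ for a perfectly
selective channel; it is deterministic given the patterns. No small-sample
bias correction is applied — scores are used for ranking, and all channels
share the same window count.

## Classifier and vote

The classifier one-hot encodes each channel's index ($16 \times K$ binary
inputs), applies one hidden layer of 20 tanh units and a softmax output,
and trains by seeded mini-batch gradient descent (batch 64, learning rate
0.2, 60 epochs) on cross-entropy, recording the full-data loss per epoch.
The output layer starts at zero, which makes training exactly equivariant
under permutations of the class order. This is the smallest architecture
that does the job; a nearest-centroid baseline is included for sanity
comparisons. Hyperparameters are exposed, and none were found critical on
separable patterns.

The majority vote is causal (trailing window, default 41 decisions) so it
is usable online; its latency is about half the span. On ties it keeps the
previous smoothed output when that label is among the tied maxima,
otherwise the earliest tied class — this preserves the invariant that the
vote never emits a label absent from its window.

Train/test splits are **block-wise in time** with a 0.25 s guard around
the split point: with 97.5 %-overlapping windows, a random per-window
split would leak nearly identical windows across the sets.

## The synthetic generator

`generate_session()` renders, per channel, $x_c(t) = a_c(t)\,e_c(t) +
n_c(t)$: $e_c$ is unit-RMS Gaussian noise band-limited to 20–450 Hz
(forward–backward order-4 Butterworth on white noise, renormalized over
the steady-state region), $a_c(t)$ the scheduled motion's target amplitude
with 100 ms linear onset ramps, and $n_c$ white noise at the 3 µV floor.
Everything is independent across channels and exactly reproducible from
the seed. Because the downstream method consumes only window RMS, matching
second-order statistics suffices; the generator is exactly calibratable —
steady-segment RMS converges to $\sqrt{a^2 + \sigma^2}$ — which the tests
exploit.

The default finger-flexion session emulates a forearm flexor-group
recording: channels 1, 4, 8 active (60 µV) in all five flexions; channel 5
active (80 µV) **only** during middle-finger flexion; one dedicated 70 µV
channel per flexion; channels 9–13 each shared by two adjacent flexions
(50 µV) so that channel 5 remains the unique middle-selective electrode;
channels 14–16 weakly common (20 µV); rest silent. The 4×4 row-major grid
is an assumption — real arrays differ — and is fully configurable through
`electrode_layout()`. Durations default to two repetitions of 6 s per
flexion with 2 s rests (≈82 s, ≈16 000 windows): a realistic short
training protocol that keeps a full five-seed end-to-end run in CI-scale
compute; the two repetitions give the block split both classes on both
sides.

What the generator does **not** emulate: motor-unit action potential
trains and their interference structure, volume conduction/crosstalk
between channels, electrode-skin impedance drift, motion artifacts, and
inter-subject variability. Passing tests therefore demonstrate the
correctness of the chain and its behavior under controlled spatial
structure — not clinical-grade accuracy on real recordings, where the
amplitude clusters are less clean and patterns drift between sessions.

## File formats

Signals, features and patterns travel as delimited text (exact, human
readable; columns `time_s, ch01.., label`); signals additionally as EDF
(the standard electrophysiology exchange format, 16-bit over a declared
physical range of ±1.05× the signal maximum — round trips are exact to
half a quantization step, with the range taken from its 8-character ASCII
header representation so reader and writer agree bit-for-bit on the
scale). Models and layouts serialize as YAML at full precision.
`run_pipeline()` writes every intermediate plus a manifest (stage seeds,
parameters, MD5 of each artifact); identical config and seed reproduce
byte-identical feature, pattern and report files.

## Known limitations

* EM convergence to the $10^{-8}$ tolerance can exceed the 500-iteration
  cap on large pooled samples (flagged, benign — see above).
* The EDF writer emits plain continuous EDF, not EDF+; per-sample labels
  do not survive the EDF round trip.
* The causal filtering mode flags but does not trim its warm-up region;
  downstream windows overlapping it are the caller's concern.
* Channel-selection scores are raw empirical MI; comparing scores across
  datasets of very different sizes would need bias correction.
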