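---
title: "Methods: hybrid DNN-HMM recognition of pig vocalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid DNN-HMM recognition of pig vocalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigvoc)
```

pigvoc classifies short single-channel recordings of pig calls into five
behavioral states. This vignette is the package's own account of the
models it implements, the choices that were genuinely open, and what the
synthetic test bed does and does not establish.

## Signal model and enhancement

Recordings are mono PCM waveforms, processed internally in double
precision on `[-1, 1]`; integer conversion happens only at WAV file
boundaries (16-bit, full scale 32768). The canonical field rate is
44.1 kHz; other rates are accepted and can be resampled with an
anti-aliased polyphase filter.

Denoising follows the classic autoregressive state-space reading of
Kalman speech enhancement. The clean signal within a 20 ms frame is
modeled as AR(p) with p = 12 by default — an order conventional for
speech-band resonance structure — so the state vector stacks the last p
clean samples, the transition matrix is the AR companion matrix refit on
every frame by Yule-Walker, the observation row is `e1'`, and process
noise enters only the newest component with the AR residual variance.
The control term in the general state equation is identically zero here:
nothing drives the sound but its own dynamics. Two numerical choices
matter:

* the covariance is re-symmetrized after every update, keeping it
  positive semi-definite through millions of steps (asserted in tests);
* the measurement-noise variance R is taken from a noise-only reference
  when one exists, and otherwise by minimum statistics as the mean power
  of the quietest 5% of frames. Ambient noise is assumed stationary at
  the clip scale.

Whether to run the filter once over a whole recording or frame-wise with
AR refits was an open choice; frame-wise refitting is used because a
single AR model cannot track formant movement across a call, and the
state is carried across frame boundaries so the output is seamless.

The enhancement claim the package makes is deliberately a *sign*, not a
magnitude: on AR-plus-white-noise inputs at 5 dB SNR the filtered output
has higher SNR than the input (mean over seeded trials). Measured gains
on that synthetic family are around +2.8 dB, but the magnitude depends
entirely on how oracle-like the AR model is for the material, so only
the improvement itself is asserted.

## Endpoint detection

Vocalizations are located by a two-level decision. The signal is first
decomposed by empirical mode decomposition: cubic-spline envelopes
through the local extrema (mirrored at the boundaries to tame edge
swings) are averaged and subtracted until the component satisfies the
IMF acceptance rule — extrema and zero-crossing counts differing by at
most one, with a normalized sift-increment threshold of 0.05 and a cap
of 60 sifts. Decomposition is exact by construction: the IMFs plus
residual always sum back to the input.

Which IMFs are "informative" is not prescribed by the method's usual
description, so two standard rules are provided: keep IMFs whose
energy-weighted mean frequency falls in a configurable band (default
0.1–14 kHz, spanning the five call classes' occupancy), or keep the
top-k IMFs by correlation with the input. The band rule is the default.
Similarly, whether the Teager operator is applied to each IMF and the
energies summed, or once to the IMF sum, is ambiguous; the sum-first
reading is the default with the per-IMF variant behind a flag.

The primary decision double-thresholds the frame-mean Teager energy.
Absolute thresholds would break on every gain change, so both are
adaptive: high = noise mean + 5 sd, low = noise mean + 2 sd, with noise
statistics from the first 100 ms. This makes detection invariant to
amplitude scaling, which is tested. The secondary decision extends
candidate boundaries outward while the short-time cepstral distance — a
Euclidean distance over quefrency bins 1–12 of the magnitude real
cepstrum, with a log floor of 1e-10 and bin 0 excluded so gain cancels —
stays above its own adaptive threshold (noise mean + 3 sd). Segments
shorter than 50 ms are dropped and gaps under 50 ms merged.

Boundary accuracy is asserted statistically: over 50 seeded synthetic
bursts at 10 dB SNR, at least 90% of boundaries fall within ±30 ms of
the generator's truth. Onsets are sharper than offsets because the
synthetic envelope releases over 30 ms, and an energy detector
necessarily triggers somewhere inside a fade.

## Features

The front end is the standard MFCC recipe: pre-emphasis with
coefficient 0.98, 20 ms frames with a 10 ms hop (full frames only, no
padding — exactly 99 frames for one second at 44.1 kHz), Hamming window,
FFT power spectrum, 26 triangular filters on the HTK mel scale spanning
0 to Nyquist, floored log energies, and an orthonormal DCT-II keeping
coefficients 0–12. Three conventions were open:

* the window (unstated in most recipes' summaries) is Hamming, the
  literature default;
* c0 is retained as the first static coefficient rather than replaced by
  log-energy, keeping the static dimension at 13 without an extra term;
* "frame overlap of 10 ms" is read as a 10 ms hop.

Dynamics use the standard regression formula with window 2 (denominator
10) and edge replication; delta-deltas apply the same operator again,
giving 13 + 13 + 13 = 39 columns. For the network, each frame is
concatenated with three frames of context on each side (edge-replicated),
giving 39 × 7 = 273 inputs.

## Acoustic models

Each class gets a left-to-right HMM: 5 states, initial distribution
fixed at `[1, 0, 0, 0, 0]`, transitions allowing only self-loop or
advance with the last state absorbing — a topology that encodes the
onset/body/offset temporal structure of a call. A printed description of
the transition matrix "summing to 1" in total is inconsistent with a
stochastic matrix; rows sum to 1 here, the only consistent reading.
Emissions are diagonal-covariance Gaussian mixtures with K = 4
components per state (the mixture size is not prescribed anywhere;
4 is small enough for desk-scale EM on 39-d features and large enough to
be a real mixture) and a variance floor of 1e-3 per dimension, the
universal guard for MFCC GMMs.

Initialization divides every training sequence into five equal-duration
blocks and pools block j across sequences for state j; k-means picks the
component means. Pooled statistics use maximum-likelihood (1/n)
variances so duplicated sequences change nothing. Baum-Welch EM then
runs for up to 40 iterations with a relative log-likelihood tolerance of
1e-6, accumulating numerators and denominators across all sequences
before dividing — the multi-sequence form, not per-sequence averaging.
All trellis math is in the log domain (the compiled forward, backward
and Viterbi kernels), which trades the scaled-alpha idiom for a simpler
correctness argument; both are exact. Components that lose all
occupancy keep their previous parameters with renormalized weights and a
warning — at K = 4 on small synthetic classes this fires routinely and
is the designed behavior, not an error.

Classification scores a segment under every class model and takes the
argmax; the Viterbi path score is the default (matching the recipe's
"best hidden-state path" description), with the forward likelihood
selectable. Ties break to the earlier model.

The EM fixture design deserves a note. The fixed-point property — EM
started at the generating parameters should barely move — is asymptotic:
at finite sample size the update lands on the empirical sufficient
statistics, whose sampling noise is the floor on any movement bound. The
fixture is therefore built so that floor sits well below the asserted
1e-3: emission sd 0.05 and self-loops of 0.9975 over 200 sequences of
2500 frames put every parameter's sampling sd near 2e-4. Likewise the
recovery fixture uses self-loops of 0.96 over 80-frame sequences so
expected state durations (~27 frames) match the even-division
initializer's assumption; with strongly unbalanced durations the
block-initialized EM can merge the short-lived states, which is a
property of the initializer, not of EM.

## Hybrid DNN-HMM

Viterbi alignment of each training clip under its own class model labels
every frame with one of 25 class-state units (class-major indexing:
unit = (class − 1) × 5 + state). A feed-forward network —
273 → 128 → 128 → 128 → 25, ReLU hidden layers, one shared 25-way
softmax output (one softmax rather than five separate ones, matching a
single shared output layer) — is trained on these labels with mean
cross-entropy. The printed update rule ascends the gradient; descent is
what minimizes the loss and is what Adam implements here (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8, learning rate 0.003, batch 100). He-normal
initialization suits the ReLU stack. The epoch/iteration pair in the
recipe ("10 epochs, 200 iterations") is honored as up to 10 passes with
at most 200 optimizer steps per pass, whichever binds first; early
stopping watches a stratified 10% validation split with a patience of 3
checks (patience is unstated anywhere and had to be fixed). Training is
bit-reproducible under a fixed seed.

At decode time, unit posteriors are converted to scaled log-likelihoods
`log p(q|x) − log p(q)`; the frame evidence term is a per-frame constant
common to all units, provably unable to change any Viterbi decision
(asserted by a perturbation test), and is dropped. Unit priors come from
alignment frame counts with add-one smoothing so no unit has zero prior.
Each class is decoded in its own 5-state trellis using its transitions
from the GMM-HMM stage — the max approximation to the full acoustic
score.

## Evaluation

One-vs-rest counts per class give recall `TP/(TP+FN)` and specificity
`1 − FP/(FP+TN)`; overall accuracy is trace/total, the multi-class
reading consistent with reporting a single accuracy; macro values are
unweighted means over classes. Classes with undefined (0/0) metrics are
excluded from macros and flagged. For two classes, recall of one class
equals specificity of the other by definition — kept as a test.

## The synthetic test bed

The generator emulates what the pipeline assumes about its material:
five classes with distinct fundamental ranges and trajectories (flat,
rising, falling, pulsed), harmonic stacks with 1/k rolloff shaped by
second-order resonators at class formants, sustained or burst-train
envelopes, lead/trail silence, and background noise (white plus a
low-frequency component band-limited below 3 kHz, where farm noise
concentrates) mixed to an exact clip-level SNR. Humming is low and
narrow-band, eating is pulsed mid-band energy, estrus and howling are
the deliberately confusable pair — sustained tonal calls with
overlapping fundamentals and formants, distinguished mainly by rising
versus falling pitch — and panting is wide-band breath pulses. Fixtures
default to 16 kHz so routine test runs stay fast; the wide-band class is
band-clipped at Nyquist there, which is documented behavior, and
everything accepts 44.1 kHz.

What passing tests show: the algorithms are correct (trellis recursions
match exhaustive enumeration; gradients match finite differences; EM is
monotone and recovers known parameters), the front end obeys its
closed-form identities, and the full train/decode chain separates
acoustically distinct classes at realistic SNR. Under the default
conditions (50 clips per class, 10 dB SNR, fixed seed) all three systems
reach ceiling accuracy on the held-out 20% — the synthetic classes,
although built with one confusable pair, remain easier than field
recordings. What passing tests do not show: robustness to real pig-barn
acoustics — overlapping animals, reverberation, non-stationary machinery
noise, recording-chain variation — or the ordering of systems on real
data, where the hybrid's advantage over GMM-HMM would have to be
re-established empirically.

## Problem sizes and numerical choices, in one place

* Routine test runs: 5–8 clips/class at 16 kHz; full acceptance runs:
  50 clips/class (250 clips, ~29k training frames), chosen as the scale
  at which class confusions would become visible while a complete run
  stays in minutes on one CPU.
* Log floors: 1e-10 (filterbank and cepstrum), posterior floor 1e-12,
  probability floor in CE 1e-12.
* Variance floor 1e-3; EM empty-occupancy guard 1e-8.
* Viterbi ties break to the lower state index; classification ties to
  the earlier model — deterministic and documented rather than random.
* Degenerate inputs: constant frames yield a flagged zero-variance AR
  model; all-zero frames get floored cepstra; silence-only clips return
  an empty segment list; an impossible observation sequence raises an
  error rather than returning −Inf silently.

## Known limitations

* The Kalman enhancer assumes locally-AR signal and stationary noise; it
  will not help against impulsive or highly non-stationary interference.
* EMD sifting is the single slowest front-end stage; long recordings
  should be segmented before decomposition.
* The DNN is a plain MLP over spliced frames by design — no
  convolutional or recurrent variants, no pretraining, no dropout — so
  its ceiling on hard material is modest; frame-level validation
  accuracy on the synthetic set (~66%) is far below clip-level accuracy
  because neighboring states within a class are genuinely ambiguous at
  frame granularity, and whole-clip Viterbi integrates over that
  ambiguity.
* Classification is whole-segment; there is no streaming decoder or
  lattice output.
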