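---
title: "PLATT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PLATT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platt)
```

This vignette explains the science implemented in **platt**: the
low-latency dynamic-range manipulation scheme itself, the functional
class-D hearing-loss model it is meant to counteract, and the scaled-down
speech-recognition-threshold (SRT) harness used to exercise the
compensation hypothesis on synthetic material. It also records the
numerical and design choices that were genuinely open, and what the
passing tests do and do not show about real speech material.

## The problem

A hearing loss can be decomposed into an *attenuation* component (class
A), which linear amplification can compensate, and a *distortion*
component (class D), which is level-independent and cannot be undone by
amplification. A functional model of the class-D component adds
i.i.d. Gaussian noise — a *level uncertainty* `u` in dB — to the
spectro-temporal feature values an automatic-speech-recognition (ASR)
system sees, and limits the usable frequency range. Since the noise acts
in the log-level domain, one way to protect information against it is to
*expand* (amplify) the spectral patterns that carry it before the noise
is added. Spectral modulation patterns of roughly 2–4 ERB extent (about
1/8–1/4 cycles per ERB) are both important for speech recognition in
noise and manipulable with only about 1 ms of lookahead, which makes
them the natural target in a hearing-device context.

## Gammatone analysis and resynthesis

The analysis filterbank has 78 complex fourth-order Gammatone channels
with center frequencies on a fixed Mel-spaced grid (123 Hz to 13943 Hz,
roughly 0.5 ERB apart). The grid carries two extra values on each end
(64, 93, 14501, 15080 Hz) purely so that every channel has grid
neighbours two positions away: a channel's −10 dB bandwidth is defined
as `grid[i + 2] − grid[i − 2]` (e.g. 221 − 93 = 128 Hz for the 155 Hz
channel). Each channel is a cascade of four identical one-pole complex
stages

\[ H(z) = \frac{b}{(1 - p\,z^{-1})^4}, \qquad
   p = \lambda\, e^{2\pi i f_c / f_s}. \]

Three design rules pin the free parameters:

* **Pole radius** λ is solved numerically (bisection on the measured
  −10 dB width of the fourth-order magnitude response) so that the
  channel meets its grid-assigned bandwidth. A closed form for λ exists
  in the literature of this filter family, but the numeric solve is
  exact with respect to the bandwidth rule by construction and is
  validated against the printed 128 Hz example.
* **Peak gain** is normalized to 2, so that a real tone at a channel's
  center frequency appears in the channel's complex output with
  magnitude equal to its own amplitude (the analytic-signal factor 1/2
  cancels the gain of 2). This makes the dB-SPL calibration of input
  and representation identical.
* **Phase alignment**: the phase of each channel's single feed-forward
  coefficient is set, propagating upward from the lowest channel (whose
  phase is 0), so that each pair of neighbouring channels is
  phase-identical at the delay where the product of their temporal
  envelopes peaks. This minimizes destructive interference when the
  channels are summed.

Resynthesis is the plain sum of the real parts of all channels. Because
neighbouring phase-aligned channels overlap, that sum has a flat but
non-unity passband gain (about +10 dB); a constant design-time
normalization (the inverse of the mean passband magnitude) is applied in
`fb_resynthesize()` so the all-pass-gain path is calibration-transparent.
The measured passband ripple of the normalized path is about 0.3 dB over
200 Hz–12 kHz; the tests assert a conservative 3 dB bound.

The joint impulse response is a downward frequency sweep: high channels
ring early, low channels late. `joint_response()` reports a per-channel
delay defined as the *energy centroid* of the channel's temporal
envelope, i.e. the arrival time of the center of the wave packet, which
equals the channel's magnitude-weighted average group delay (about
2.4 ms near 2 kHz and 4.3 ms near 800 Hz at 48 kHz). The
envelope-*maximum* time is also returned; for the skewed Gammatone
envelope it is systematically earlier (2.0/3.7 ms), while the resonant
group delay is later (2.7/5.0 ms). The centroid is used as the package's
delay figure because it is the standard envelope-delay measure and the
one a reader takes from a plotted wave packet.

Per-channel gains are applied at the audio rate, obtained from the 1 kHz
gain trajectories by zero-order hold followed by a slew limiter of 24 dB
per period of the channel's center frequency (i.e. `24 fc/fs` dB per
sample). The slew limiter alone defines the audible contract; no
additional interpolation is applied because any smoother upsampling
would only relax an already-met bound.

## The spectro-temporal representation

For each channel the instantaneous amplitude (the magnitude of the
complex band signal) is tracked by a hold/decay automaton: a new local
maximum is taken instantaneously, held for 15 ms, and then decays at
1 dB/ms until the current amplitude overtakes it (which restarts the
hold — including on exactly equal values). The hold guarantees that
downsampling to any rate above ~67 Hz loses no local maximum; the
package uses 1000 Hz, i.e. one 78-value spectral frame per millisecond.
Levels are expressed in dB SPL under the convention that a full-scale
sine is 120 dB SPL (configurable, `calibration_dbspl_fs`), and floored
at the normal-hearing threshold (ISO 226:2003 values, vendored as a
breakpoint table and interpolated on a log-frequency axis). The
automaton is pinned down by a per-sample oracle test; using the
magnitude rather than the real part as "instantaneous amplitude" is an
interpretation — it extracts the same held maxima without half-cycle
ripple.

## The adaptive gain engine

Each spectral frame is convolved (along frequency, in dB) with unit-sum
Hanning windows of widths 8, 16, 32 and 64 channels — about 2, 4, 8 and
16 ERB full width at half maximum at the 0.5 ERB channel spacing. The
successive differences

```
d1 = frame − s8,  d2 = s8 − s16,  d3 = s16 − s32,  d4 = s32 − s64
```

are spectral-modulation band-pass layers (d1 above 1/4 cycles/ERB, d2
1/4–1/8, d3 1/8–1/16, d4 1/16–1/32), and `base = s64` is the base
layer; their sum reconstructs the frame exactly. Two boundary choices
are the package's own: reflection padding (avoids spurious edge
roll-off in the base layer), and a zero-phase realization of the
even-width windows (the average of the two half-sample alignments —
an asymmetric placement would shift every layer by half a channel).

The desired output levels are built in a fixed order:

1. the base layer, mapped affinely from the input dynamic range
   `[in_low, in_high]` to the output range `[out_low, out_high]`
   (or left unchanged in identity mode);
2. plus d1, unconditionally;
3. plus `E · d2`, unconditionally, where `E ≥ 1` is the expansion
   factor — the knob that hardens 2–4 ERB patterns against level
   uncertainty;
4. plus `f3 ⊙ d3`, then `f4 ⊙ d4`, where each factor vector is the
   largest per-channel α ∈ [0, 1] whose addition keeps the current
   output inside the output range, *after* propagation of the
   strongest compression along frequency: `f_j = min(raw_j,
   min_k raw_k + 1 − w(j − k))` with a peak-normalized Hann taper `w`
   (FWHM 6 channels for d3, 12 for d4, support ±FWHM). A raw factor of
   0 at 2708 Hz caps the factors at 2346/3112 Hz to 0.5 and leaves
   channels below 2023 Hz and above 3565 Hz untouched.

The gain is the difference between desired output and input frame. The
default input range is 105 dB SPL on top and a 25–30 dB SPL bottom
curve (25 between 500 Hz and 4 kHz, 30 below 250 Hz and above 8 kHz,
interpolated in log-frequency — the plateau values are given, the
interpolation is the package's choice). Note that d1 and d2 are added
*unconditionally* by design: desired levels may exceed the output
limits; only d3/d4 factors enforce them. A single propagation pass is
used; the pass is deliberately not idempotent (the Hann taper cost is
not subadditive), which matches the worked example above.

On the extreme two-tone input (500 Hz + 2000 Hz, any level in the input
range) the layer dynamics stay small: at most ≈7 dB encoded in d1 and
≈8 dB in d2 — the "dynamic" of a layer being its one-sided maximum
magnitude. This is why expanding d2 by factors up to 8 costs little
dynamic range while substantially raising the 2–4 ERB contrast.

## Class-D listener profiles

The feature front end is a DCT-free log-Mel spectrogram: 25 ms Hann
windows every 10 ms, 36 triangular Mel filters spanning 64 Hz–16 kHz,
10·log10, offset to the dB-SPL calibration. Its level convention is
anchored to tone amplitude; a broadband tone at a channel's center
reads within ~2 dB of its presentation level, and adding G dB of gain
to the audio shifts every value by exactly G — the property that makes
the profile degradations class D. A `listener_profile("P-<flim>-<u>")`
applies, in fixed order: removal of channels above the frequency limit,
an optional absolute-threshold floor, and the level-uncertainty noise
(per-utterance seeds derived from a master seed, drawn independently at
every feature computation — information once removed stays removed).

## The SRT harness

The harness mirrors the structure of an ASR-based speech-test
simulation: for every training SNR, noisy (optionally PLATT-processed)
tokens are turned into profile-degraded features and summarized into
per-word templates; disjoint test tokens are then classified at every
test SNR, giving a recognition-result map of word-correct percentage
over the training × test SNR grid (3 dB steps). The SRT for a target
rate is the lowest interpolated crossing along the test axis, minimized
over training SNRs; rows whose first grid point already exceeds the
target are flagged left-censored, and maps that never reach the target
yield an explicit no-SRT result. Plomp curves (SRT versus masker
presentation level) and the benefit — the mean unaided-minus-aided SRT
improvement at 70/80/90 dB SPL, levels at which linear amplification
cannot help — summarize conditions; psychometric segments evaluate
SRT-20…SRT-90 in 5 % steps.

The classifier is a deliberate stand-in: diagonal-Gaussian per-word
templates over time-pooled log-Mel statistics (per-channel mean and
mean absolute frame-to-frame delta). A full GMM–HMM recognizer with a
sentence language model is out of scope; the harness keeps the
*procedure* (training-SNR × test-SNR map → interpolated SRT) while
using a classifier of adequate, replaceable power. Conditions are
simulated completely independently of each other; nothing is shared or
calibrated across conditions.

### Synthetic material

All inputs are generated, seeded and calibrated in-package:

* `speech_shaped_noise()` — Gaussian noise shaped by an embedded
  long-term-average-speech-spectrum breakpoint curve (plateau to
  500 Hz, −6 dB/octave above): the stationary masker stand-in.
* `fluctuating_noise()` — the same spectrum split into three bands
  (crossovers 800/2500 Hz), each gated by an independent speech-like
  on/off envelope (bursts 100–300 ms, pauses 80–180 ms, 20 ms ramps,
  −40 dB pause floor): a co-modulated masker with syllabic (2–8 Hz)
  modulation and no pause longer than 250 ms.
* `synthetic_word_corpus()` — a closed vocabulary of formant-like
  templates (2–3 tone glides plus an optional onset burst, 300–600 ms);
  tokens jitter ±5 % in time and ±1 semitone in pitch.

These stand-ins reproduce the *properties* the method cares about
(spectral shape, stationarity versus co-modulation, a separable closed
vocabulary) but not real speech: no phonetic confusability, no talker
variability, no linguistic redundancy. Passing harness tests therefore
demonstrate that the machinery behaves as designed and that the
direction of the effects is as hypothesized — not that the numeric
benefits transfer to a real matrix test, which would require the
original corpus and recognizer.

### Problem sizes and study conditions

The harness tests run at a reduced scale chosen to keep the full suite
comfortably desk-sized: 10 words × 20 tokens at 32 kHz (half of each
word's tokens for training), training SNRs −15…−3 dB, test SNRs
−27…+3 dB in 3 dB steps, the stationary masker at 70 dB SPL, and two
independent level-uncertainty draws per test token so that every grid
point aggregates 200 classification decisions. With these conditions
the simulated SRT-50 rises monotonically with the level uncertainty
(u = 1, 7, 14, 21 dB; the strongest profile does not reach 50 % at all
within the grid), expansion by a factor 6 improves the SRT by several
dB for u = 14 while changing it by well under 1 dB for u = 1, and a
transparent configuration (expansion 1, output range equal to input
range) changes the SRT by about 1 dB — the harness's Monte-Carlo noise
floor.

## Numerical choices and degenerate inputs

* Filter design is cached per sample rate; sample rates below twice the
  top grid frequency (2 × 15080 Hz) are rejected.
* Silence maps to −Inf before threshold flooring; every represented
  level is at least the channel's hearing threshold.
* `conditional_factor()` returns 1 for a zero difference, 0 when the
  current value already violates the limit in the difference's
  direction; out-of-range values moving inward get the largest factor
  that does not overshoot the far limit.
* Template variances in the classifier are floored at 1e-3 dB² to keep
  degenerate dimensions from dominating likelihoods.
* Non-integer audio-rate/1 kHz ratios fall back to linear interpolation
  at the frame instants; integer ratios decimate exactly.
* Seeds are kept below 2^31; all generators restore the caller's RNG
  state.

## Known limitations

* The expansion factor is global — frequency- or level-dependent
  expansion is explicitly out of scope.
* The harness's absolute SRT values depend on the synthetic corpus and
  stand-in classifier; only within-harness comparisons (orderings,
  benefits) are meaningful.
* Binaural processing, real-time block processing and fixed-point
  arithmetic are not modeled.
* The fluctuating masker caps pauses by construction rather than
  reproducing any published gating algorithm.

## A worked example

```{r example, eval = FALSE}
fb <- design_filterbank(48000)
fb$bandwidth_10db_hz[fb$center_freq_hz == 155]   # 128

x <- pure_tone(500, 65, 0.25, 48000) + pure_tone(2000, 65, 0.25, 48000)
et <- envelope_track(fb_analyze(x, fb), fb)
ld <- decompose_layers(et$levels_db_spl[200, ])
max(abs(ld$d2))                                   # about 7.7 dB

y <- platt_process(x, 48000,
                   platt_config(expansion_factor = 6,
                                base_map = "identity"))
```
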