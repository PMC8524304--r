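# platt

Low-latency auditory dynamic-range manipulation and speech-recognition-
threshold (SRT) simulation in R.

**platt** is for computational-audiology and hearing-device researchers
who want to study *class-D* hearing losses — the distortion component
that linear amplification cannot compensate — and a candidate
compensation strategy for them. It implements:

* **PLATT**, a dynamic-range manipulation scheme built on a 78-channel
  complex fourth-order Gammatone filterbank (half-ERB spacing, trivial
  time-domain resynthesis, ~1 ms algorithmic lookahead). Each 1 ms
  spectral frame is decomposed into a base layer and four
  spectral-modulation difference layers by Hanning smoothing across
  frequency; the 2–4 ERB modulation band (`d2`) can be *expanded* by a
  factor `E` while coarser layers are conditionally compressed into a
  configurable output dynamic range:

  ```
  out = map(base) + d1 + E·d2 + f3⊙d3 + f4⊙d4,   gain = out − frame
  ```

  with `f3`, `f4` the largest per-channel factors in [0, 1] that keep
  `out` inside the output range, propagated along frequency by a Hann
  taper (FWHM 6 and 12 channels). Gains are applied with a slew limit
  of 24 dB per period of each channel's center frequency.

* A functional **class-D hearing-loss model** in a log-Mel feature
  domain (36 channels, 25 ms/10 ms): listener profiles `P-<flim>-<u>`
  combine an upper frequency limit (1000–8000 Hz) with a level
  uncertainty `u` (1–21 dB of i.i.d. Gaussian noise added to the
  log-domain features) — both level-independent degradations.

* A scaled-down **SRT evaluation harness**: seeded synthetic fixtures
  (calibrated tones, speech-shaped stationary noise, 3-band
  co-modulated fluctuating noise, a jittered synthetic word corpus), a
  diagonal-Gaussian word classifier over a training-SNR × test-SNR
  grid, recognition-result maps, interpolated SRTs, Plomp curves,
  benefit averages and psychometric segments.

## Worked example

```r
library(platt)

fb <- design_filterbank(48000)
fb$bandwidth_10db_hz[fb$center_freq_hz == 155]
#> [1] 128          # -10 dB bandwidth from the grid rule (221 - 93 Hz)

jr <- joint_response(fb)
round(jr$delay_ms[which.min(abs(jr$channel_freq_hz - 2000))], 2)
#> [1] 2.37         # envelope delay near 2 kHz, ms (downward sweep)

# two tones, full analysis chain, spectral-modulation layers
x <- pure_tone(500, 65, 0.25, 48000) + pure_tone(2000, 65, 0.25, 48000)
et <- envelope_track(fb_analyze(x, fb), fb)
ld <- decompose_layers(et$levels_db_spl[200, ])
round(max(abs(ld$d2)), 2)
#> [1] 7.72         # dynamic encoded in the 2-4 ERB layer, dB (< 9)

# process noisy audio with expansion factor 6
y <- platt_process(x, 48000, platt_config(expansion_factor = 6,
                                          base_map = "identity"))

# a small recognition experiment under a class-D profile
corp <- synthetic_word_corpus(10, 20, seed = 11, sample_rate_hz = 32000)
map <- simulate_recognition_map(corp, "stationary", 70,
                                listener_profile("P-8000-14"),
                                train_snrs_db = seq(-15, -3, 3),
                                test_snrs_db = seq(-27, 3, 3), seed = 21)
srt_from_map(map, 50)
#> SRT-50: 1.5 dB SNR [best training SNR -3 dB]
```

The SRT printed for a `P-8000-14` profile is far above the ~−13 dB a
near-normal `P-8000-1` profile reaches in the same condition; processing
the mixtures with `platt_config(expansion_factor = 6, base_map =
"identity")` before feature extraction recovers several dB of that gap,
while changing the near-normal result by well under 1 dB. The methods
vignette (`vignettes/platt-methods.Rmd`) describes the models, defaults
and design decisions in detail.

## Command line

A thin CLI over the same functions lives at `inst/cli/platt.R`:

```sh
Rscript inst/cli/platt.R process --in x.wav --out y.wav --expansion 6 \
        --base-map identity
Rscript inst/cli/platt.R synth --kind fluctuating --level 70 --seed 1 \
        --out m.wav
Rscript inst/cli/platt.R simulate --profile P-2000-14 --masker stationary \
        --level 70 --expansion 6 --seed 7 --out results/
```

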