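# Seeded generators for calibrated synthetic fixtures: pure tones,
# speech-shaped stationary noise, 3-band co-modulated fluctuating noise,
# a synthetic word corpus, and SNR mixing.

#' Broadband signal level in dB SPL
#'
#' RMS level under the calibration convention that a full-scale sine
#' (amplitude 1, RMS 1/sqrt(2)) corresponds to `calibration_dbspl_fs`
#' dB SPL.
#'
#' @param x Numeric vector of audio samples.
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @return Level in dB SPL.
#' @export
signal_level_db_spl <- function(x, calibration_dbspl_fs = 120) {
  calibration_dbspl_fs + 20 * log10(sqrt(mean(x^2)) * sqrt(2))
}

# scale x to the requested RMS level
.scale_to_level <- function(x, level_db_spl, calibration_dbspl_fs = 120) {
  x * 10^((level_db_spl - signal_level_db_spl(x, calibration_dbspl_fs)) / 20)
}

#' Calibrated pure tone
#'
#' @param freq_hz Tone frequency (below Nyquist).
#' @param level_db_spl Presentation level in dB SPL.
#' @param duration_s Duration in seconds.
#' @param sample_rate_hz Sample rate in Hz.
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @return Numeric vector: a sine of amplitude
#'   `10^((level - calibration) / 20)`.
#' @export
#' @examples
#' x <- pure_tone(1000, 120, 0.1, 48000)
#' max(abs(x))   # 1 (full scale)
pure_tone <- function(freq_hz, level_db_spl, duration_s, sample_rate_hz,
                      calibration_dbspl_fs = 120) {
  if (freq_hz >= sample_rate_hz / 2) stop("tone frequency above Nyquist")
  a <- 10^((level_db_spl - calibration_dbspl_fs) / 20)
  t <- seq(0, duration_s - 1 / sample_rate_hz, by = 1 / sample_rate_hz)
  a * sin(2 * pi * freq_hz * t)
}

# long-term-average-speech-spectrum breakpoint table (dB, relative):
# gentle low-frequency roll-off, plateau around 250-500 Hz, -6 dB/octave
# above 500 Hz
.ltass_freq_hz <- c(50, 80, 125, 250, 500, 1000, 2000, 4000, 8000, 16000)
.ltass_db <- c(-20, -10, -4, -1, 0, -6, -12, -18, -24, -30)

# spectrally shape white Gaussian noise by the LTASS curve (FFT domain)
.shaped_noise <- function(n, fs) {
  fs <- as.numeric(fs)
  x <- rnorm(n)
  X <- fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)                    # two-sided spectrum
  g <- 10^(approx(log(.ltass_freq_hz), .ltass_db, xout = log(pmax(f, 1)),
                  rule = 2)$y / 20)
  g[f < 40] <- 0                          # no DC / infrasound
  Re(fft(X * g, inverse = TRUE)) / n
}

#' Speech-shaped stationary noise
#'
#' Gaussian noise spectrally shaped by an embedded long-term-average
#' speech spectrum (plateau up to 500 Hz, -6 dB/octave above). This is the
#' package's stationary test-specific masker: same long-term spectral
#' shape as speech-like material, negligible envelope fluctuation.
#'
#' @param level_db_spl Presentation level in dB SPL (RMS).
#' @param duration_s Duration in seconds.
#' @param seed Integer seed; realizations are reproducible per seed.
#' @param sample_rate_hz Sample rate in Hz (default 48000).
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @return Numeric vector of audio samples.
#' @export
speech_shaped_noise <- function(level_db_spl, duration_s, seed,
                                sample_rate_hz = 48000,
                                calibration_dbspl_fs = 120) {
  n <- round(duration_s * sample_rate_hz)
  x <- with_seed(seed, .shaped_noise(n, sample_rate_hz))
  .scale_to_level(x, level_db_spl, calibration_dbspl_fs)
}

# speech-like on/off gain envelope: bursts of 100-300 ms separated by
# pauses of 80-180 ms (well below the 250 ms cap), 20 ms raised-cosine
# ramps, pause floor -40 dB
.syllabic_envelope <- function(n, fs) {
  ramp_n <- round(0.020 * fs)
  floor_lin <- 10^(-40 / 20)
  env <- numeric(0)
  while (length(env) < n + ramp_n) {
    on_n <- round(runif(1, 0.10, 0.30) * fs)
    off_n <- round(runif(1, 0.08, 0.18) * fs)
    ramp <- 0.5 - 0.5 * cos(pi * (1:ramp_n) / ramp_n)
    up <- floor_lin + (1 - floor_lin) * ramp
    seg <- c(up, rep(1, on_n), rev(up), rep(floor_lin, off_n))
    env <- c(env, seg)
  }
  env[1:n]
}

#' Co-modulated fluctuating noise
#'
#' Speech-shaped noise split into three frequency bands (crossovers at 800
#' and 2500 Hz), each multiplied by an independent speech-like on/off
#' envelope at syllabic rates (about 2-8 Hz); no pause exceeds 250 ms in
#' any band. This is the package's fluctuating masker with high envelope
#' dynamics, standing in for an ICRA-style co-modulated noise.
#'
#' @inheritParams speech_shaped_noise
#' @return Numeric vector of audio samples.
#' @export
fluctuating_noise <- function(level_db_spl, duration_s, seed,
                              sample_rate_hz = 48000,
                              calibration_dbspl_fs = 120) {
  fs <- as.numeric(sample_rate_hz)
  n <- round(duration_s * fs)
  out <- with_seed(seed, {
    base <- .shaped_noise(n, fs)
    X <- fft(base)
    f <- (0:(n - 1)) * fs / n
    f <- pmin(f, fs - f)
    xover <- function(f, fc, width = 0.2) {  # raised-cosine crossfade
      lo <- fc * (1 - width); hi <- fc * (1 + width)
      w <- (f - lo) / (hi - lo)
      0.5 * (1 - cos(pi * pmin(1, pmax(0, w))))
    }
    h1 <- 1 - xover(f, 800)
    h3 <- xover(f, 2500)
    h2 <- pmax(0, 1 - h1 - h3)
    y <- 0
    for (h in list(h1, h2, h3)) {
      band <- Re(fft(X * h, inverse = TRUE)) / n
      y <- y + band * .syllabic_envelope(n, fs)
    }
    y
  })
  .scale_to_level(out, level_db_spl, calibration_dbspl_fs)
}

# one synthetic word template: 2-3 formant-like tone glides plus an
# optional onset noise burst; parameters drawn once per word
.word_template <- function() {
  list(duration_s = runif(1, 0.30, 0.60),
       n_glides = sample(2:3, 1),
       f_start = exp(runif(3, log(300), log(3200))),
       f_end = exp(runif(3, log(300), log(3200))),
       glide_gain_db = runif(3, -6, 0),
       burst = runif(1) < 0.7,
       burst_freq = runif(1, 1000, 6000),
       burst_gain_db = -6)
}

.render_token <- function(tpl, fs, time_scale = 1, pitch_shift = 1) {
  dur <- tpl$duration_s * time_scale
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  env <- sin(pi * t / dur)^2              # smooth on/off
  y <- numeric(n)
  for (g in seq_len(tpl$n_glides)) {
    f0 <- tpl$f_start[g] * pitch_shift
    f1 <- tpl$f_end[g] * pitch_shift
    finst <- f0 + (f1 - f0) * t / dur     # linear glide
    phase <- 2 * pi * cumsum(finst) / fs
    y <- y + 10^(tpl$glide_gain_db[g] / 20) * sin(phase) * env
  }
  if (tpl$burst) {
    bn <- round(0.06 * fs)
    burst <- rnorm(bn)
    k <- seq(0, bn - 1)
    mod <- sin(2 * pi * tpl$burst_freq * pitch_shift * k / fs)
    burst <- burst * mod * sin(pi * k / bn)
    y[1:bn] <- y[1:bn] + 10^(tpl$burst_gain_db / 20) * burst
  }
  y
}

#' Synthetic word corpus
#'
#' Generates a labeled corpus of synthetic "words": each word is a distinct
#' formant-like spectro-temporal template (two to three tone glides plus an
#' optional onset noise burst, 300-600 ms), and each token is a jittered
#' realization of its word's template (time scale within +-5 %, pitch
#' within +-1 semitone). All draws are deterministic per seed. This is a
#' scaled-down stand-in for a closed-set matrix-test vocabulary.
#'
#' @param n_words Number of distinct words (>= 2; default 10).
#' @param n_tokens Tokens per word (default 20).
#' @param seed Integer seed.
#' @param sample_rate_hz Sample rate in Hz (default 48000).
#' @param level_db_spl Nominal presentation level of each token (RMS,
#'   default 65 dB SPL).
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @return An object of class `platt_corpus`: list with `tokens` (list of
#'   `list(word, audio)`), `n_words`, `n_tokens`, `sample_rate_hz`,
#'   `level_db_spl`.
#' @export
synthetic_word_corpus <- function(n_words = 10, n_tokens = 20, seed = 1,
                                  sample_rate_hz = 48000,
                                  level_db_spl = 65,
                                  calibration_dbspl_fs = 120) {
  stopifnot(n_words >= 2)
  fs <- sample_rate_hz
  tokens <- with_seed(seed, {
    templates <- replicate(n_words, .word_template(), simplify = FALSE)
    out <- vector("list", n_words * n_tokens)
    i <- 0
    for (w in seq_len(n_words)) {
      for (tk in seq_len(n_tokens)) {
        i <- i + 1
        y <- .render_token(templates[[w]], fs,
                           time_scale = runif(1, 0.95, 1.05),
                           pitch_shift = 2^(runif(1, -1, 1) / 12))
        out[[i]] <- list(word = w,
                         audio = .scale_to_level(y, level_db_spl,
                                                 calibration_dbspl_fs))
      }
    }
    out
  })
  structure(list(tokens = tokens, n_words = n_words, n_tokens = n_tokens,
                 sample_rate_hz = fs, level_db_spl = level_db_spl),
            class = "platt_corpus")
}

#' @export
print.platt_corpus <- function(x, ...) {
  cat("synthetic word corpus: ", x$n_words, " words x ", x$n_tokens,
      " tokens @ ", x$sample_rate_hz, " Hz, ", x$level_db_spl,
      " dB SPL\n", sep = "")
  invisible(x)
}

#' Mix speech and masker at a given SNR
#'
#' Scales the masker to its presentation level and the speech to
#' `masker_level_db_spl + snr_db`, takes a (seeded) random masker fragment
#' of the speech's length, and sums. With `snr_db = Inf` the scaled speech
#' is returned alone.
#'
#' @param speech,masker Numeric audio vectors; the masker must be at least
#'   as long as the speech.
#' @param snr_db Signal-to-noise ratio in dB.
#' @param masker_level_db_spl Masker presentation level in dB SPL.
#' @param seed Optional integer seed for the fragment choice (`NULL`: the
#'   fragment starts at the beginning).
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @return Numeric vector of the mixture, same length as `speech`. A
#'   warning is raised if the mixture exceeds full scale.
#' @export
mix_at_snr <- function(speech, masker, snr_db, masker_level_db_spl,
                       seed = NULL, calibration_dbspl_fs = 120) {
  n <- length(speech)
  if (length(masker) < n) stop("masker shorter than speech")
  if (is.infinite(snr_db) && snr_db > 0) return(speech)
  sp <- .scale_to_level(speech, masker_level_db_spl + snr_db,
                        calibration_dbspl_fs)
  mk <- .scale_to_level(masker, masker_level_db_spl, calibration_dbspl_fs)
  off <- if (is.null(seed)) 0 else
    with_seed(seed, sample.int(length(masker) - n + 1, 1) - 1)
  out <- sp + mk[off + 1:n]
  if (max(abs(out)) > 1) {
    warning("mixture exceeds full scale (", round(max(abs(out)), 2), ")")
  }
  out
}
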