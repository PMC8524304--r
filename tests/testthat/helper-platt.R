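# Shared fixtures and independent oracles for the test suite.
# design_filterbank() caches per sample rate, so repeated calls are cheap.

fb48 <- function() design_filterbank(48000)

# analytic Gammatone impulse response of channel k (independent closed
# form: h[n] = b * C(n+3, 3) * p^n)
gt_impulse_oracle <- function(fb, k, n) {
  i <- 0:(n - 1)
  fb$fir_coeff[k] * choose(i + 3, 3) * fb$pole[k]^i
}

# brute-force per-sample hold/decay automaton on one amplitude sequence
track_oracle <- function(a, fs, hold_ms = 15, decay_db_per_ms = 1) {
  hold_n <- round(hold_ms * fs / 1000)
  decay <- 10^(-decay_db_per_ms / (20 * fs / 1000))
  held <- 0
  timer <- 0
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    if (a[i] >= held) {
      held <- a[i]
      timer <- hold_n
    } else if (timer > 0) {
      timer <- timer - 1
    } else {
      held <- held * decay
      if (a[i] >= held) {
        held <- a[i]
        timer <- hold_n
      }
    }
    out[i] <- held
  }
  out
}

# direct-convolution smoothing oracle: reflect-pad then convolve with the
# zero-phase kernel built from first principles (average of the two
# alignments of the n interior Hann samples, unit sum)
smooth_oracle <- function(x, width) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(width) / (width + 1))
  w <- w / sum(w)
  k <- (c(w, 0) + c(0, w)) / 2
  half <- width / 2
  xp <- c(x[(half + 1):2], x, x[(length(x) - 1):(length(x) - half)])
  out <- numeric(length(x))
  for (j in seq_along(x)) {
    out[j] <- sum(k * xp[j:(j + 2 * half)])
  }
  out
}

# exhaustive O(n^2) factor propagation oracle
propagate_oracle <- function(raw, fwhm) {
  n <- length(raw)
  w <- function(d) ifelse(abs(d) > fwhm, 0, 0.5 * (1 + cos(pi * d / fwhm)))
  out <- numeric(n)
  for (j in seq_len(n)) {
    caps <- vapply(seq_len(n), function(k) raw[k] + 1 - w(j - k),
                   numeric(1))
    out[j] <- min(raw[j], min(caps))
  }
  pmin(1, pmax(0, out))
}

# exhaustive SRT scan oracle: for every training row find the lowest
# rising crossing of the target along the test axis, then take the minimum
srt_oracle <- function(correct_pct, test_snrs, target) {
  best <- Inf
  for (r in seq_len(nrow(correct_pct))) {
    p <- correct_pct[r, ]
    if (p[1] >= target) {
      best <- min(best, test_snrs[1])
      next
    }
    for (i in seq_len(length(p) - 1)) {
      if (p[i] < target && p[i + 1] >= target) {
        s <- test_snrs[i] + (target - p[i]) / (p[i + 1] - p[i]) *
          (test_snrs[i + 1] - test_snrs[i])
        best <- min(best, s)
        break
      }
    }
  }
  if (is.infinite(best)) NA_real_ else best
}

# steady-state two-tone spectral frame through the real chain
two_tone_frame <- function(fb, level_db_spl, f1 = 500, f2 = 2000,
                           dur = 0.25) {
  fs <- fb$sample_rate_hz
  x <- pure_tone(f1, level_db_spl, dur, fs) +
    pure_tone(f2, level_db_spl, dur, fs)
  et <- envelope_track(fb_analyze(x, fb), fb)
  et$levels_db_spl[round(dur * 800), ]
}
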