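# Gammatone filterbank design, analysis and resynthesis.
#
# Each channel is a fourth-order complex Gammatone filter realized as a
# cascade of four identical first-order stages with pole p = lambda *
# exp(2 pi i fc / fs) and a single complex feed-forward coefficient b:
#
#   H(z) = b / (1 - p z^-1)^4
#
# lambda is set so that the -10 dB bandwidth of |H| equals the grid
# difference two positions right minus two positions left of the channel's
# center frequency; |b| normalizes the peak gain to 2; arg(b) aligns the
# phases of neighbouring channels where the product of their temporal
# envelopes peaks, which minimizes destructive interference in the summed
# (resynthesized) output.

# 4th-order magnitude response of the un-normalized cascade
.gt_mag4 <- function(f, fc, lambda, fs) {
  (1 / Mod(1 - lambda * exp(2i * pi * fc / fs) * exp(-2i * pi * f / fs)))^4
}

# measured -10 dB full bandwidth (Hz) for a given pole radius; returns fs
# when the response is too broad to have -10 dB points (drives the solver
# towards larger lambda)
.gt_measured_bw10 <- function(lambda, fc, fs) {
  opt <- optimize(function(f) -.gt_mag4(f, fc, lambda, fs),
                  c(max(1, fc / 4), min(fs / 2 - 1, fc * 4)))
  fpk <- opt$minimum
  target <- -opt$objective * 10^(-10 / 20)
  g <- function(f) .gt_mag4(f, fc, lambda, fs) - target
  if (g(1e-3) > 0 || g(fs / 2 - 1) > 0) return(fs)
  lo <- uniroot(g, c(1e-3, fpk), tol = 1e-9)$root
  hi <- uniroot(g, c(fpk, fs / 2 - 1), tol = 1e-9)$root
  hi - lo
}

.gt_solve_lambda <- function(fc, bw, fs) {
  uniroot(function(l) .gt_measured_bw10(l, fc, fs) - bw,
          c(0.3, 1 - 1e-8), tol = 1e-12)$root
}

# analytic impulse response of one normalized channel, length n samples:
# h[n] = b * C(n+3, 3) * p^n
.gt_impulse <- function(b, pole, n) {
  k <- 0:(n - 1)
  b * choose(k + 3, 3) * pole^k
}

#' Design the half-ERB-spaced Gammatone filterbank
#'
#' Designs the 78-channel complex fourth-order Gammatone filterbank on the
#' fixed Mel-spaced grid of [frequency_grid()]. For each channel the -10 dB
#' bandwidth is the difference of the grid frequencies two positions right
#' and left of its center (e.g. 221 - 93 = 128 Hz for the 155 Hz channel);
#' the pole radius is found by numeric root-finding on this bandwidth
#' condition, the feed-forward coefficient magnitude normalizes the peak
#' transfer gain to 2, and its phase is propagated from the lowest channel
#' upward so that each pair of neighbouring filters is phase-identical at
#' the delay where the product of their temporal envelopes peaks.
#'
#' Designs are cached per sample rate within the session.
#'
#' @param sample_rate_hz Audio sample rate in Hz; must be at least twice the
#'   top grid frequency (2 x 15080 Hz). Default 48000.
#' @return An object of class `gammatone_fb`: a list with elements
#'   `sample_rate_hz`, `grid_freqs_hz` (82), `center_freq_hz` (78),
#'   `bandwidth_10db_hz` (78), `pole` (complex, 78), `fir_coeff` (complex,
#'   78), `order` (4) and `resynth_norm` (constant passband normalization of
#'   the resynthesis sum).
#' @export
#' @examples
#' fb <- design_filterbank(48000)
#' fb$bandwidth_10db_hz[fb$center_freq_hz == 155]   # 128
design_filterbank <- function(sample_rate_hz = 48000) {
  grid <- frequency_grid()
  if (sample_rate_hz < 2 * max(grid)) {
    stop("sample_rate_hz must be at least ", 2 * max(grid),
         " Hz (twice the top grid frequency)")
  }
  key <- paste0("fb_", format(sample_rate_hz, digits = 12))
  if (!is.null(.platt_cache[[key]])) return(.platt_cache[[key]])

  fs <- sample_rate_hz
  idx <- 3:(length(grid) - 2)
  fc <- grid[idx]
  bw <- grid[idx + 2] - grid[idx - 2]
  nch <- length(fc)

  lambda <- mapply(.gt_solve_lambda, fc, bw, MoreArgs = list(fs = fs))
  theta <- 2 * pi * fc / fs
  pole <- lambda * exp(1i * theta)

  # peak-gain normalization to 2
  peak <- vapply(seq_len(nch), function(k) {
    opt <- optimize(function(f) -.gt_mag4(f, fc[k], lambda[k], fs),
                    c(max(1, fc[k] / 4), min(fs / 2 - 1, fc[k] * 4)))
    -opt$objective
  }, numeric(1))
  bmag <- 2 / peak

  # phase alignment: for each neighbouring pair find the delay n* where the
  # product of the 4th-order temporal envelopes C(n+3,3)^2 (lam_k lam_k+1)^n
  # peaks, and rotate the upper channel's FIR phase so both phases agree
  # there (the phase of channel k at delay n is arg(b_k) + n theta_k)
  nmax <- round(0.05 * fs)
  nseq <- 0:nmax
  lc <- lchoose(nseq + 3, 3)
  phi <- numeric(nch)
  for (k in seq_len(nch - 1)) {
    lenv <- 2 * lc + nseq * (log(lambda[k]) + log(lambda[k + 1]))
    nstar <- nseq[which.max(lenv)]
    phi[k + 1] <- (phi[k] + nstar * (theta[k] - theta[k + 1])) %% (2 * pi)
  }
  fir <- bmag * exp(1i * phi)

  fb <- structure(list(
    sample_rate_hz = fs,
    grid_freqs_hz = grid,
    center_freq_hz = fc,
    bandwidth_10db_hz = bw,
    pole = pole,
    fir_coeff = fir,
    order = 4L,
    resynth_norm = 1
  ), class = "gammatone_fb")

  # constant resynthesis normalization: mean magnitude of the summed real
  # impulse responses over the flat part of the passband
  jr <- .joint_spectrum(fb)
  band <- jr$freq_hz >= 200 & jr$freq_hz <= 12000
  fb$resynth_norm <- 1 / mean(jr$magnitude[band])

  .platt_cache[[key]] <- fb
  fb
}

#' @export
print.gammatone_fb <- function(x, ...) {
  cat("Gammatone filterbank: ", length(x$center_freq_hz),
      " complex 4th-order channels, ", x$center_freq_hz[1], "-",
      x$center_freq_hz[length(x$center_freq_hz)], " Hz @ ",
      x$sample_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

# magnitude spectrum of the summed real impulse responses (un-normalized)
.joint_spectrum <- function(fb, n_fft = 2^17) {
  fs <- fb$sample_rate_hz
  nmax <- round(0.05 * fs)
  k <- 0:(nmax - 1)
  h <- vapply(seq_along(fb$center_freq_hz), function(c) {
    Re(.gt_impulse(fb$fir_coeff[c], fb$pole[c], nmax))
  }, numeric(nmax))
  joint <- rowSums(h)
  H <- fft(c(joint, rep(0, n_fft - length(joint))))
  nf <- n_fft %/% 2
  list(freq_hz = (0:(nf - 1)) * fs / n_fft,
       magnitude = Mod(H[1:nf]),
       joint_ir = joint)
}

#' Filterbank analysis
#'
#' Filters a real signal with every channel's four-stage first-order complex
#' IIR cascade times its feed-forward coefficient. A pure tone at a channel's
#' center frequency appears in that channel's real part at (approximately)
#' unchanged amplitude, so the dB-SPL calibration of input and band signals
#' is identical.
#'
#' @param signal Numeric vector of finite audio samples.
#' @param fb A `gammatone_fb` from [design_filterbank()].
#' @return Complex matrix, channels x samples (78 x length(signal)).
#' @export
fb_analyze <- function(signal, fb) {
  stopifnot(inherits(fb, "gammatone_fb"))
  if (length(signal) == 0) {
    return(matrix(complex(0), nrow = length(fb$center_freq_hz), ncol = 0))
  }
  if (!all(is.finite(signal))) stop("signal contains non-finite samples")
  gt_cascade_cpp(as.numeric(signal), fb$pole, fb$fir_coeff)
}

#' Resynthesis with time-varying per-channel gains
#'
#' Sums the real parts of all band signals, each multiplied by a per-sample
#' linear gain obtained from the 1 kHz gain trajectories by zero-order hold
#' followed by a slew limiter: the applied gain changes by at most
#' `max_db_per_period` dB per period of the channel's center frequency
#' (i.e. `max_db_per_period * fc / fs` dB per sample), which limits channel
#' crosstalk. A constant design-time normalization makes the all-pass-gain
#' path calibration-transparent.
#'
#' @param bands Complex band matrix from [fb_analyze()] (channels x samples).
#' @param gains_db Numeric matrix of per-channel gain trajectories in dB at
#'   the representation rate (channels x frames), or `NULL` for 0 dB.
#' @param fb The `gammatone_fb` used for analysis.
#' @param frame_rate_hz Rate of the gain trajectories (default 1000 Hz).
#' @param max_db_per_period Slew limit in dB per center-frequency period
#'   (default 24).
#' @return Numeric vector of audio samples.
#' @export
fb_resynthesize <- function(bands, gains_db = NULL, fb,
                            frame_rate_hz = 1000, max_db_per_period = 24) {
  stopifnot(inherits(fb, "gammatone_fb"))
  nch <- length(fb$center_freq_hz)
  if (nrow(bands) != nch) {
    stop("bands has ", nrow(bands), " rows; filterbank has ", nch,
         " channels")
  }
  if (is.null(gains_db)) gains_db <- matrix(0, nch, 1)
  if (nrow(gains_db) != nch) {
    stop("gains_db has ", nrow(gains_db), " rows; filterbank has ", nch,
         " channels")
  }
  resynthesize_cpp(bands, gains_db, fb$sample_rate_hz, frame_rate_hz,
                   fb$center_freq_hz, max_db_per_period, fb$resynth_norm)
}

#' Applied (slew-limited) gain trajectories
#'
#' Expands 1 kHz gain trajectories to audio rate exactly as
#' [fb_resynthesize()] applies them: zero-order hold followed by the
#' per-channel slew limiter. Useful for verifying the rate-limit contract.
#'
#' @inheritParams fb_resynthesize
#' @param n_samples Number of audio samples to expand to.
#' @return Numeric matrix, channels x `n_samples`, applied gain in dB.
#' @export
applied_gain <- function(gains_db, n_samples, fb, frame_rate_hz = 1000,
                         max_db_per_period = 24) {
  stopifnot(inherits(fb, "gammatone_fb"))
  applied_gain_cpp(gains_db, as.integer(n_samples), fb$sample_rate_hz,
                   frame_rate_hz, fb$center_freq_hz, max_db_per_period)
}

#' Joint analysis-resynthesis response
#'
#' Characterizes the all-pass-gain system: the magnitude spectrum of the
#' summed (normalized) real impulse responses, and the frequency-dependent
#' delay of the joint downward-sweeping impulse response. The per-channel
#' delay is the temporal-envelope energy centroid of the channel's impulse
#' response (the arrival time of the center of the wave packet, equal to the
#' channel's magnitude-weighted average group delay); the envelope-peak time
#' is also returned. Delays of the skewed Gammatone envelope satisfy
#' peak < centroid < resonant group delay.
#'
#' @param fb A `gammatone_fb`.
#' @param n_fft FFT length for the magnitude spectrum.
#' @return A list with `freq_hz` and `magnitude_db` (spectrum of the
#'   normalized joint response), `channel_freq_hz`, `delay_ms`
#'   (energy-centroid envelope delay per channel) and `delay_peak_ms`
#'   (envelope-maximum delay per channel).
#' @export
#' @examples
#' fb <- design_filterbank(48000)
#' jr <- joint_response(fb)
#' jr$delay_ms[which.min(abs(jr$channel_freq_hz - 2000))]  # about 2.4 ms
joint_response <- function(fb, n_fft = 2^17) {
  stopifnot(inherits(fb, "gammatone_fb"))
  fs <- fb$sample_rate_hz
  js <- .joint_spectrum(fb, n_fft)
  nmax <- round(0.05 * fs)
  k <- 0:(nmax - 1)
  delay <- matrix(0, length(fb$center_freq_hz), 2)
  for (c in seq_along(fb$center_freq_hz)) {
    e2 <- Mod(.gt_impulse(fb$fir_coeff[c], fb$pole[c], nmax))^2
    delay[c, 1] <- sum(k * e2) / sum(e2) / fs * 1000
    delay[c, 2] <- (which.max(e2) - 1) / fs * 1000
  }
  list(freq_hz = js$freq_hz,
       magnitude_db = 20 * log10(js$magnitude * fb$resynth_norm),
       channel_freq_hz = fb$center_freq_hz,
       delay_ms = delay[, 1],
       delay_peak_ms = delay[, 2])
}
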