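# Log-Mel feature front end and the class-D hearing-loss manipulations
# (frequency limiting, absolute threshold, level uncertainty) applied to it.

.mel <- function(f) 2595 * log10(1 + f / 700)
.mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

# triangular Mel filterbank, peak-normalized; returns weights (bins x nch)
# and the channel center frequencies
.mel_filterbank <- function(n_channels, fmin, fmax, nfft, fs) {
  edges <- .mel_inv(seq(.mel(fmin), .mel(fmax), length.out = n_channels + 2))
  fbin <- (0:(nfft / 2)) * fs / nfft
  W <- matrix(0, length(fbin), n_channels)
  for (c in seq_len(n_channels)) {
    lo <- edges[c]; ce <- edges[c + 1]; hi <- edges[c + 2]
    up <- fbin >= lo & fbin <= ce
    down <- fbin > ce & fbin <= hi
    W[up, c] <- (fbin[up] - lo) / (ce - lo)
    W[down, c] <- (hi - fbin[down]) / (hi - ce)
  }
  list(weights = W, center_freq_hz = edges[2:(n_channels + 1)])
}

#' Log Mel-spectrogram
#'
#' MFCC-style front end without the cepstral transform: 25 ms Hann-windowed
#' frames every 10 ms, power spectrum pooled by triangular Mel filters
#' (default 36 channels spanning 64 Hz to 16 kHz), expressed in dB. Levels
#' are offset to the dB-SPL calibration: a tone at a channel center
#' frequency reads within about 2 dB of its presentation level (window
#' leakage pooled by the triangle accounts for the offset), and adding
#' G dB of gain to the audio shifts every value by exactly G.
#'
#' @param audio Numeric vector of calibrated audio samples.
#' @param sample_rate_hz Sample rate in Hz (at least 32 kHz so the 16 kHz
#'   Mel span is covered).
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @param n_channels Number of Mel channels (default 36).
#' @param window_ms,shift_ms Analysis window and shift (defaults 25, 10).
#' @return An object of class `log_mel`: list with `values_db` (matrix
#'   n_frames x n_channels), `channel_freqs_hz`, `window_ms`, `shift_ms`.
#' @export
log_mel_spectrogram <- function(audio, sample_rate_hz,
                                calibration_dbspl_fs = 120,
                                n_channels = 36, window_ms = 25,
                                shift_ms = 10) {
  fs <- sample_rate_hz
  win <- round(window_ms / 1000 * fs)
  shift <- round(shift_ms / 1000 * fs)
  n <- length(audio)
  if (n < win) stop("signal shorter than one analysis window")
  nf <- (n - win) %/% shift + 1
  nfft <- nextn(win, 2)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  starts <- (0:(nf - 1)) * shift
  Fm <- matrix(0, nfft, nf)
  for (j in seq_len(nf)) Fm[1:win, j] <- audio[starts[j] + 1:win] * w
  X <- mvfft(Fm)[1:(nfft / 2 + 1), , drop = FALSE]
  # amplitude-calibrated power: a bin containing a sine of amplitude A
  # reads A^2
  P <- (2 * Mod(X) / sum(w))^2
  mb <- .mel_filterbank(n_channels, 64, min(16000, fs / 2), nfft, fs)
  Pm <- crossprod(P, mb$weights)          # frames x channels
  vals <- 10 * log10(pmax(Pm, 1e-300)) + calibration_dbspl_fs
  structure(list(values_db = vals,
                 channel_freqs_hz = mb$center_freq_hz,
                 window_ms = window_ms, shift_ms = shift_ms),
            class = "log_mel")
}

#' @export
print.log_mel <- function(x, ...) {
  cat("log Mel-spectrogram: ", nrow(x$values_db), " frames x ",
      ncol(x$values_db), " channels (", round(x$channel_freqs_hz[1]), "-",
      round(x$channel_freqs_hz[length(x$channel_freqs_hz)]), " Hz)\n",
      sep = "")
  invisible(x)
}

#' Add level uncertainty to a feature matrix
#'
#' Adds i.i.d. Gaussian noise with standard deviation `u_db` to every
#' time-frequency bin -- the functional class-D hearing-loss mechanism.
#' Because the noise acts in the log-level domain it is level-independent:
#' linear amplification of the audio cannot undo it.
#'
#' @param lms A `log_mel` object.
#' @param u_db Level uncertainty (standard deviation in dB, >= 0).
#' @param seed Integer seed; the draw is reproducible per seed.
#' @return A `log_mel` with perturbed values.
#' @export
apply_level_uncertainty <- function(lms, u_db, seed) {
  stopifnot(inherits(lms, "log_mel"), u_db >= 0)
  if (u_db == 0) return(lms)
  v <- lms$values_db
  noise <- with_seed(seed, matrix(rnorm(length(v), 0, u_db), nrow(v)))
  lms$values_db <- v + noise
  lms
}

#' Limit the frequency range of a feature matrix
#'
#' Removes all channels with center frequency above `limit_freq_hz`,
#' emulating a steeply sloping hearing loss above the limit.
#'
#' @param lms A `log_mel` object.
#' @param limit_freq_hz Upper frequency limit in Hz.
#' @return A `log_mel` with the remaining channels.
#' @export
apply_frequency_limit <- function(lms, limit_freq_hz) {
  stopifnot(inherits(lms, "log_mel"))
  keep <- lms$channel_freqs_hz <= limit_freq_hz
  if (!any(keep)) stop("limit_freq_hz is below the lowest Mel channel")
  lms$values_db <- lms$values_db[, keep, drop = FALSE]
  lms$channel_freqs_hz <- lms$channel_freqs_hz[keep]
  lms
}

#' Floor a feature matrix at an absolute hearing threshold
#'
#' Replaces values below the per-channel threshold (audiogram) by the
#' threshold value, the class-A component of a hearing loss.
#'
#' @param lms A `log_mel` object.
#' @param audiogram Per-channel threshold vector in dB (recycled scalar
#'   allowed).
#' @return A `log_mel` with floored values.
#' @export
apply_absolute_threshold <- function(lms, audiogram) {
  stopifnot(inherits(lms, "log_mel"))
  nch <- ncol(lms$values_db)
  if (length(audiogram) == 1) audiogram <- rep(audiogram, nch)
  stopifnot(length(audiogram) == nch)
  lms$values_db <- pmax(lms$values_db, rep(audiogram,
                                           each = nrow(lms$values_db)))
  lms
}

#' Class-D listener profile
#'
#' A listener profile "P-\<flim\>-\<u\>" combines an upper frequency limit
#' (1000, 2000, 4000 or 8000 Hz) with a frequency-independent level
#' uncertainty (1, 7, 14 or 21 dB). Both manipulations remove information
#' from the feature representation in a level-independent way and so induce
#' a class-D loss.
#'
#' @param name Profile name such as `"P-2000-14"`, or `NULL` to give the
#'   parameters directly.
#' @param limit_freq_hz Upper frequency limit in Hz.
#' @param level_uncertainty_db Level uncertainty in dB.
#' @param audiogram Optional per-channel absolute threshold (class-A
#'   component), applied after the frequency limit.
#' @return An object of class `listener_profile`.
#' @export
#' @examples
#' listener_profile("P-2000-14")
listener_profile <- function(name = NULL, limit_freq_hz = 8000,
                             level_uncertainty_db = 1, audiogram = NULL) {
  if (!is.null(name)) {
    parts <- strsplit(name, "-", fixed = TRUE)[[1]]
    if (length(parts) != 3 || parts[1] != "P") {
      stop("profile name must have the form 'P-<flim>-<u>'")
    }
    limit_freq_hz <- as.numeric(parts[2])
    level_uncertainty_db <- as.numeric(parts[3])
  }
  structure(list(
    name = sprintf("P-%g-%g", limit_freq_hz, level_uncertainty_db),
    limit_freq_hz = limit_freq_hz,
    level_uncertainty_db = level_uncertainty_db,
    audiogram = audiogram), class = "listener_profile")
}

#' @export
print.listener_profile <- function(x, ...) {
  cat("listener profile ", x$name, ": frequency limit ", x$limit_freq_hz,
      " Hz, level uncertainty ", x$level_uncertainty_db, " dB\n", sep = "")
  invisible(x)
}

#' Apply a listener profile to a feature matrix
#'
#' Composition order: frequency limit, then absolute threshold (if any),
#' then level uncertainty.
#'
#' @param lms A `log_mel` object.
#' @param profile A [listener_profile()].
#' @param seed Seed for the level-uncertainty draw.
#' @return A `log_mel` with the profile's degradations applied.
#' @export
apply_listener_profile <- function(lms, profile, seed) {
  stopifnot(inherits(profile, "listener_profile"))
  lms <- apply_frequency_limit(lms, profile$limit_freq_hz)
  if (!is.null(profile$audiogram)) {
    lms <- apply_absolute_threshold(lms, profile$audiogram)
  }
  apply_level_uncertainty(lms, profile$level_uncertainty_db, seed)
}

#' Run code with a temporary RNG seed
#'
#' Evaluates an expression under `set.seed(seed)` and restores the caller's
#' RNG state afterwards, so seeded generators do not disturb the global
#' random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Export a log-Mel feature matrix as CSV
#'
#' Writes the feature values with a header row of Mel channel center
#' frequencies.
#'
#' @param lms A `log_mel` object.
#' @param path Output file path.
#' @export
write_log_mel_csv <- function(lms, path) {
  stopifnot(inherits(lms, "log_mel"))
  m <- lms$values_db
  colnames(m) <- round(lms$channel_freqs_hz, 1)
  write.csv(m, path, row.names = FALSE)
}
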