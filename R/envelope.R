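# Spectro-temporal representation: hold/decay envelope tracking, dB-SPL
# conversion, normal-hearing-threshold flooring, 1 kHz downsampling.

# ISO 226:2003 threshold of hearing (free field, binaural, frontal
# incidence), vendored as a breakpoint table; interpolated linearly on a
# log-frequency axis and clamped to the nearest entry outside its range.
.iso226_freq_hz <- c(20, 25, 31.5, 40, 50, 63, 80, 100, 125, 160, 200, 250,
                     315, 400, 500, 630, 800, 1000, 1250, 1600, 2000, 2500,
                     3150, 4000, 5000, 6300, 8000, 10000, 12500)
.iso226_thr_db <- c(78.5, 68.7, 59.5, 51.1, 44.0, 37.5, 31.5, 26.5, 22.1,
                    17.9, 14.4, 11.4, 8.6, 6.2, 4.4, 3.0, 2.2, 2.4, 3.5,
                    1.7, -1.3, -4.2, -6.0, -5.4, -1.5, 6.0, 12.6, 13.9, 12.3)

#' Normal-hearing threshold at given frequencies
#'
#' Threshold of hearing according to ISO 226:2003, interpolated to arbitrary
#' frequencies on a log-frequency axis (clamped to the nearest table entry
#' outside 20 Hz - 12.5 kHz).
#'
#' @param freqs_hz Numeric vector of frequencies in Hz.
#' @return Numeric vector of thresholds in dB SPL.
#' @export
hearing_threshold_db_spl <- function(freqs_hz) {
  approx(log(.iso226_freq_hz), .iso226_thr_db, xout = log(freqs_hz),
         rule = 2)$y
}

#' Hold/decay envelope tracking
#'
#' Runs the PLATT envelope automaton on the instantaneous amplitude
#' (magnitude) of each band signal: every new local maximum is taken
#' instantaneously and held for `hold_ms`; afterwards the held value decays
#' at `decay_db_per_ms` until overtaken by the current amplitude (which
#' restarts the hold). This removes the temporal fine structure while
#' preserving onsets.
#'
#' @param bands Complex band matrix from [fb_analyze()], or a real
#'   amplitude matrix (channels x samples).
#' @param sample_rate_hz Audio sample rate in Hz.
#' @param hold_ms Hold duration in ms (default 15).
#' @param decay_db_per_ms Decay rate in dB per ms (default 1).
#' @return Numeric matrix of tracked amplitudes, channels x samples.
#' @export
track_envelope <- function(bands, sample_rate_hz, hold_ms = 15,
                           decay_db_per_ms = 1) {
  amp <- if (is.complex(bands)) band_magnitude_cpp(bands) else abs(bands)
  if (!is.matrix(amp)) amp <- matrix(amp, nrow = 1)
  track_envelope_cpp(amp, sample_rate_hz, hold_ms, decay_db_per_ms)
}

#' Amplitude to dB SPL
#'
#' Converts linear amplitudes to dB SPL under the calibration convention
#' that a full-scale sine (amplitude 1.0) corresponds to
#' `calibration_dbspl_fs` dB SPL. Non-positive amplitudes map to `-Inf`.
#'
#' @param amplitudes Numeric vector or matrix of amplitudes.
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @return dB SPL values with the same shape as `amplitudes`.
#' @export
amp_to_db_spl <- function(amplitudes, calibration_dbspl_fs = 120) {
  out <- ifelse(amplitudes > 0, 20 * log10(amplitudes), -Inf)
  out + calibration_dbspl_fs
}

#' Floor levels at the normal-hearing threshold
#'
#' Replaces every level below the normal-hearing threshold of its channel by
#' the threshold value, removing spectro-temporal modulations that are not
#' perceivable by normal-hearing listeners.
#'
#' @param levels_db_spl Numeric matrix of levels (channels x frames, or
#'   frames x channels -- see `channels_in_rows`).
#' @param channel_freqs_hz Channel center frequencies in Hz.
#' @param channels_in_rows If `TRUE` (default) rows are channels.
#' @return Floored matrix of the same shape.
#' @export
apply_hearing_floor <- function(levels_db_spl,
                                channel_freqs_hz = channel_freqs(),
                                channels_in_rows = TRUE) {
  thr <- hearing_threshold_db_spl(channel_freqs_hz)
  if (is.matrix(levels_db_spl)) {
    if (channels_in_rows) {
      stopifnot(nrow(levels_db_spl) == length(thr))
      pmax(levels_db_spl, thr)
    } else {
      stopifnot(ncol(levels_db_spl) == length(thr))
      pmax(levels_db_spl, rep(thr, each = nrow(levels_db_spl)))
    }
  } else {
    stopifnot(length(levels_db_spl) == length(thr))
    pmax(levels_db_spl, thr)
  }
}

#' Downsample tracked amplitudes to the representation rate
#'
#' Keeps every (fs / rate)-th sample of the tracked amplitudes. Because the
#' tracker holds every local maximum for at least 15 ms, downsampling to
#' 1000 Hz (or any rate above about 67 Hz) loses no held maximum. For
#' non-integer decimation factors the trajectories are sampled at the frame
#' instants by linear interpolation.
#'
#' @param tracked Numeric matrix from [track_envelope()] (channels x
#'   samples).
#' @param sample_rate_hz Audio sample rate in Hz.
#' @param frame_rate_hz Target representation rate (default 1000 Hz).
#' @return Numeric matrix, channels x n_frames.
#' @export
downsample_to_1khz <- function(tracked, sample_rate_hz,
                               frame_rate_hz = 1000) {
  n <- ncol(tracked)
  d <- sample_rate_hz / frame_rate_hz
  if (abs(d - round(d)) < 1e-9) {
    idx <- seq(round(d), n, by = round(d))
    tracked[, idx, drop = FALSE]
  } else {
    tt <- seq(d, n, by = d)
    t(apply(tracked, 1, function(x) approx(seq_len(n), x, xout = tt)$y))
  }
}

#' Extract the PLATT spectro-temporal representation
#'
#' Full envelope chain: hold/decay tracking of the band magnitudes,
#' downsampling to the representation rate, conversion to dB SPL, and
#' flooring at the normal-hearing threshold.
#'
#' @param bands Complex band matrix from [fb_analyze()].
#' @param fb The `gammatone_fb` used for analysis.
#' @param calibration_dbspl_fs dB SPL of a full-scale sine (default 120).
#' @param frame_rate_hz Representation rate in Hz (default 1000).
#' @return An object of class `envelope_track`: list with `levels_db_spl`
#'   (matrix n_frames x 78), `frame_rate_hz` and `channel_freqs_hz`.
#' @export
envelope_track <- function(bands, fb, calibration_dbspl_fs = 120,
                           frame_rate_hz = 1000) {
  stopifnot(inherits(fb, "gammatone_fb"))
  tracked <- track_envelope(bands, fb$sample_rate_hz)
  frames <- downsample_to_1khz(tracked, fb$sample_rate_hz, frame_rate_hz)
  lev <- amp_to_db_spl(frames, calibration_dbspl_fs)
  lev <- apply_hearing_floor(lev, fb$center_freq_hz, channels_in_rows = TRUE)
  structure(list(levels_db_spl = t(lev),
                 frame_rate_hz = frame_rate_hz,
                 channel_freqs_hz = fb$center_freq_hz),
            class = "envelope_track")
}

#' @export
print.envelope_track <- function(x, ...) {
  cat("PLATT spectro-temporal representation: ",
      nrow(x$levels_db_spl), " frames x ", ncol(x$levels_db_spl),
      " channels @ ", x$frame_rate_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Export an envelope track as CSV
#'
#' Writes the level matrix with a header row of channel center frequencies.
#'
#' @param x An `envelope_track`.
#' @param path Output file path.
#' @export
write_envelope_csv <- function(x, path) {
  stopifnot(inherits(x, "envelope_track"))
  m <- x$levels_db_spl
  colnames(m) <- x$channel_freqs_hz
  write.csv(m, path, row.names = FALSE)
}
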