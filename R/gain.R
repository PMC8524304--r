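# The PLATT gain engine: spectral-modulation layer decomposition of each
# spectral frame, base-layer mapping, expansion of difference 2,
# conditional re-addition of differences 3 and 4 with factor propagation.

# zero-phase smoothing kernel for an even "width n" Hanning window: the two
# half-sample-offset alignments of the n interior Hann samples are
# averaged, giving an odd symmetric unit-sum kernel of length n + 1
.smooth_kernel <- function(width) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(width) / (width + 1))
  w <- w / sum(w)
  (c(w, 0) + c(0, w)) / 2
}

# smoothing matrix S (n x n) with symmetric-reflection boundary handling;
# row j gathers the kernel weights from the (reflected) neighbourhood of
# channel j, so every row sums to 1; smoothed = S %*% frame for a column
# vector, or frame %*% t(S) for row-frames
.smoothing_matrix <- function(width, n = 78) {
  key <- paste0("smooth_", width, "_", n)
  if (!is.null(.platt_cache[[key]])) return(.platt_cache[[key]])
  k <- .smooth_kernel(width)
  half <- (length(k) - 1) / 2
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    pos <- j + (-half:half)
    pos <- ifelse(pos < 1, 2 - pos, pos)
    pos <- ifelse(pos > n, 2 * n - pos, pos)
    for (i in seq_along(k)) S[j, pos[i]] <- S[j, pos[i]] + k[i]
  }
  .platt_cache[[key]] <- S
  S
}

#' Spectral-modulation low-pass smoothing of a spectral frame
#'
#' Convolves a 78-value spectral frame (dB levels across channels) with a
#' unit-sum Hanning window of the given width; boundaries are handled by
#' symmetric reflection. Widths 8, 16, 32 and 64 samples correspond to a
#' full width at half maximum of about 2, 4, 8 and 16 ERB at the 0.5 ERB
#' channel spacing.
#'
#' @param frame Numeric vector of 78 dB levels (or a frames x 78 matrix).
#' @param width Window width: one of 8, 16, 32, 64.
#' @return Smoothed frame(s), same shape as the input.
#' @export
smooth_spectrum <- function(frame, width) {
  stopifnot(width %% 2 == 0, width <= 78)
  if (is.matrix(frame)) {
    S <- .smoothing_matrix(width, ncol(frame))
    frame %*% t(S)
  } else {
    S <- .smoothing_matrix(width, length(frame))
    as.vector(S %*% frame)
  }
}

#' Decompose a spectral frame into base and difference layers
#'
#' Computes increasingly smoothed versions s8, s16, s32, s64 of the frame
#' (Hanning widths 8, 16, 32, 64) and their successive differences:
#' d1 = frame - s8, d2 = s8 - s16, d3 = s16 - s32, d4 = s32 - s64; the base
#' layer is s64. The differences act as spectral-modulation band-pass
#' filters (d1 above 1/4 cycles/ERB, d2 between 1/4 and 1/8, d3 between 1/8
#' and 1/16, d4 between 1/16 and 1/32), and base + d4 + d3 + d2 + d1
#' reconstructs the frame exactly.
#'
#' @param frame Numeric vector of 78 dB levels.
#' @return An object of class `layer_decomposition`: list with `base`,
#'   `d1`, `d2`, `d3`, `d4` (each length 78).
#' @export
#' @examples
#' x <- sin(seq_len(78) / 4) * 10 + 60
#' ld <- decompose_layers(x)
#' max(abs(ld$base + ld$d4 + ld$d3 + ld$d2 + ld$d1 - x))  # ~1e-15
decompose_layers <- function(frame) {
  s8 <- smooth_spectrum(frame, 8)
  s16 <- smooth_spectrum(frame, 16)
  s32 <- smooth_spectrum(frame, 32)
  s64 <- smooth_spectrum(frame, 64)
  structure(list(base = s64,
                 d1 = frame - s8,
                 d2 = s8 - s16,
                 d3 = s16 - s32,
                 d4 = s32 - s64),
            class = "layer_decomposition")
}

# matrix variant: frames in rows; returns list of matrices
.decompose_layers_mat <- function(M) {
  s8 <- smooth_spectrum(M, 8)
  s16 <- smooth_spectrum(M, 16)
  s32 <- smooth_spectrum(M, 32)
  s64 <- smooth_spectrum(M, 64)
  list(base = s64, d1 = M - s8, d2 = s8 - s16, d3 = s16 - s32,
       d4 = s32 - s64)
}

#' Per-channel input/output dynamic-range limits
#'
#' Constructs the dynamic-range specification governing the base-layer
#' mapping and the conditional addition of differences 3 and 4. The default
#' input range is the one assumed relevant for normal-hearing listeners: an
#' upper limit of 105 dB SPL at all frequencies, and a lower limit of
#' 25 dB SPL from 500 Hz to 4 kHz and 30 dB SPL below 250 Hz and above
#' 8 kHz, interpolated linearly on a log-frequency axis in between. The
#' output range defaults to the input range.
#'
#' @param channel_freqs_hz Channel center frequencies (default the 78
#'   filterbank channels).
#' @param in_low,in_high,out_low,out_high Scalars, per-channel vectors, or
#'   (for the lower limits) `NULL` to use the default curve.
#' @return An object of class `dynamic_range_spec`: list of four
#'   per-channel vectors `in_low`, `in_high`, `out_low`, `out_high`.
#' @export
dynamic_range_spec <- function(channel_freqs_hz = channel_freqs(),
                               in_low = NULL, in_high = 105,
                               out_low = NULL, out_high = NULL) {
  n <- length(channel_freqs_hz)
  default_low <- approx(log(c(20, 250, 500, 4000, 8000, 24000)),
                        c(30, 30, 25, 25, 30, 30),
                        xout = log(channel_freqs_hz), rule = 2)$y
  expand <- function(x, fallback) {
    if (is.null(x)) x <- fallback
    if (length(x) == 1) x <- rep(x, n)
    stopifnot(length(x) == n)
    x
  }
  in_low <- expand(in_low, default_low)
  in_high <- expand(in_high, 105)
  out_low <- expand(out_low, in_low)
  out_high <- expand(out_high, in_high)
  if (any(in_low >= in_high) || any(out_low >= out_high)) {
    stop("dynamic range limits must satisfy low < high per channel")
  }
  structure(list(in_low = in_low, in_high = in_high,
                 out_low = out_low, out_high = out_high,
                 channel_freqs_hz = channel_freqs_hz),
            class = "dynamic_range_spec")
}

#' Map the base layer to the output dynamic range
#'
#' Either maps each channel affinely from `[in_low, in_high]` to
#' `[out_low, out_high]` (`mode = "linear"`) or leaves it unchanged
#' (`mode = "identity"`).
#'
#' @param base Base-layer vector (or frames x channels matrix).
#' @param drs A [dynamic_range_spec()].
#' @param mode `"linear"` or `"identity"`.
#' @return Mapped base layer, same shape as `base`.
#' @export
map_base_layer <- function(base, drs, mode = c("linear", "identity")) {
  mode <- match.arg(mode)
  if (mode == "identity") return(base)
  slope <- (drs$out_high - drs$out_low) / (drs$in_high - drs$in_low)
  if (is.matrix(base)) {
    sweep(sweep(base, 2, drs$in_low), 2, slope, `*`) +
      rep(drs$out_low, each = nrow(base))
  } else {
    drs$out_low + (base - drs$in_low) * slope
  }
}

#' Conditional addition factor for a difference layer
#'
#' For each channel, the largest factor alpha in `[0, 1]` such that
#' `current + alpha * diff` stays within `[out_low, out_high]`. A zero
#' difference gives factor 1; a channel already at (or beyond) the limit in
#' the difference's direction gives factor 0.
#'
#' @param current Current output levels (vector or frames x channels
#'   matrix).
#' @param diff Difference layer to be added (same shape).
#' @param drs A [dynamic_range_spec()].
#' @return Raw factor(s) in `[0, 1]`, same shape as `current`.
#' @export
#' @examples
#' drs <- dynamic_range_spec(1000, in_low = 25, out_low = 25,
#'                           in_high = 105, out_high = 90)
#' conditional_factor(80, 30, drs)   # 1/3
conditional_factor <- function(current, diff, drs) {
  if (is.matrix(current)) {
    hi <- rep(drs$out_high, each = nrow(current))
    lo <- rep(drs$out_low, each = nrow(current))
  } else {
    hi <- drs$out_high
    lo <- drs$out_low
  }
  a <- ifelse(diff > 0, (hi - current) / diff,
              ifelse(diff < 0, (lo - current) / diff, 1))
  pmin(1, pmax(0, a))
}

# peak-normalized Hann taper with the FWHM semantics of the propagation
# rule: w(0) = 1, w(+-fwhm/2) = 0.5, w = 0 beyond +-fwhm
.propagation_taper <- function(fwhm) {
  d <- -fwhm:fwhm
  w <- 0.5 * (1 + cos(pi * d / fwhm))
  list(offsets = d, w = w)
}

#' Propagate compression factors along the frequency axis
#'
#' Caps each channel's raw factor by the neighbourhood minimum plus the
#' complement of a peak-normalized Hanning taper:
#' `f_j = min(raw_j, min_k (raw_k + 1 - w(j - k)))`, clipped to `[0, 1]`,
#' where `w(0) = 1`, `w(+-fwhm/2) = 0.5` and `w = 0` beyond `+-fwhm`
#' channels. This spreads the strongest compression to neighbouring
#' channels so that already-added higher spectral modulations are not
#' re-introduced at region boundaries.
#'
#' @param raw_factors Vector (or frames x channels matrix) of raw factors
#'   in `[0, 1]`.
#' @param fwhm Full width at half maximum of the taper in channels: 6 for
#'   difference 3, 12 for difference 4.
#' @return Capped factors, same shape, elementwise no larger than the
#'   input.
#' @export
#' @examples
#' raw <- rep(1, 78)
#' raw[channel_freqs() == 2708] <- 0
#' f <- propagate_factors(raw, fwhm = 6)
#' f[channel_freqs() %in% c(2346, 3112)]   # 0.5 0.5
propagate_factors <- function(raw_factors, fwhm) {
  vec <- !is.matrix(raw_factors)
  F <- if (vec) matrix(raw_factors, nrow = 1) else raw_factors
  n <- ncol(F)
  tap <- .propagation_taper(fwhm)
  out <- F
  for (i in seq_along(tap$offsets)) {
    s <- tap$offsets[i]
    if (s == 0) next
    cost <- 1 - tap$w[i]
    # channel j is capped by raw factor at channel j - s
    src <- seq_len(n) - s
    ok <- src >= 1 & src <= n
    cand <- matrix(Inf, nrow(F), n)
    cand[, ok] <- F[, src[ok], drop = FALSE] + cost
    out <- pmin(out, cand)
  }
  out <- pmin(1, pmax(0, out))
  if (vec) as.vector(out) else out
}

#' Expansion / mapping configuration for the gain engine
#'
#' @param factor Expansion factor (>= 1) applied to difference layer 2
#'   before re-addition. Factors of 2-8 harden 2-4 ERB spectral patterns
#'   against level uncertainty.
#' @param base_map `"linear"` (affine input-to-output range mapping) or
#'   `"identity"`.
#' @return An object of class `expansion_config`.
#' @export
expansion_config <- function(factor = 1,
                             base_map = c("linear", "identity")) {
  stopifnot(is.numeric(factor), length(factor) == 1, factor >= 1)
  structure(list(factor = factor, base_map = match.arg(base_map)),
            class = "expansion_config")
}

#' Compute the per-channel gain for one spectral frame
#'
#' The desired spectral output levels are the mapped base layer plus the
#' unconditionally added differences 1 and 2 (difference 2 multiplied by
#' the expansion factor), plus differences 3 and then 4, each multiplied by
#' its conditional factor after propagation (FWHM 6 for difference 3, 12
#' for difference 4). The returned gain is desired output minus input
#' frame. Differences 1 and 2 may exceed the output limits by design; only
#' the factors for differences 3 and 4 enforce them.
#'
#' @param frame Spectral frame: vector of 78 dB-SPL levels.
#' @param drs A [dynamic_range_spec()].
#' @param cfg An [expansion_config()].
#' @return Numeric vector of 78 gains in dB.
#' @export
compute_frame_gain <- function(frame, drs, cfg = expansion_config()) {
  as.vector(.compute_gains_mat(matrix(frame, nrow = 1), drs, cfg))
}

# vectorized gain computation, frames in rows
.compute_gains_mat <- function(M, drs, cfg) {
  ld <- .decompose_layers_mat(M)
  out <- map_base_layer(ld$base, drs, cfg$base_map) +
    ld$d1 + cfg$factor * ld$d2
  f3 <- propagate_factors(conditional_factor(out, ld$d3, drs), fwhm = 6)
  out <- out + f3 * ld$d3
  f4 <- propagate_factors(conditional_factor(out, ld$d4, drs), fwhm = 12)
  out <- out + f4 * ld$d4
  out - M
}
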