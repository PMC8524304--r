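#' Mel-spaced analysis frequency grid
#'
#' The 82 fixed grid frequencies used by the filterbank design. The grid is
#' spaced equidistantly on a Mel scale with half the channel distance commonly
#' used for MFCC front ends, covering 64 Hz to 15080 Hz. Only the 78 interior
#' frequencies (123 Hz to 13943 Hz, grid positions 3 to 80) become Gammatone
#' channels; the two outermost values on each side exist so that every channel
#' has grid neighbours two positions to either side, from which its -10 dB
#' bandwidth is taken.
#'
#' The values are embedded constants, not re-derived from a Mel formula, so
#' that the design is bit-stable across platforms.
#'
#' @return Numeric vector of 82 strictly increasing frequencies in Hz.
#' @export
#' @examples
#' g <- frequency_grid()
#' length(g)   # 82
#' range(g)    # 64 .. 15080
frequency_grid <- function() {
  c(64, 93, 123, 155, 187, 221, 256, 293, 330, 370, 410, 453, 496, 542,
    589, 638, 689, 742, 797, 854, 914, 975, 1039, 1105, 1174, 1245, 1319,
    1396, 1476, 1559, 1645, 1734, 1827, 1923, 2023, 2127, 2235, 2346,
    2462, 2583, 2708, 2838, 2972, 3112, 3257, 3408, 3565, 3727, 3896,
    4071, 4253, 4441, 4637, 4840, 5051, 5270, 5498, 5734, 5979, 6233,
    6497, 6771, 7056, 7352, 7658, 7977, 8307, 8650, 9006, 9376, 9760,
    10158, 10572, 11001, 11447, 11909, 12390, 12888, 13406, 13943, 14501,
    15080)
}

#' Channel center frequencies
#'
#' The 78 Gammatone channel center frequencies (grid positions 3 to 80 of
#' [frequency_grid()]), spaced approximately 0.5 ERB apart.
#'
#' @return Numeric vector of 78 frequencies in Hz (123 to 13943).
#' @export
channel_freqs <- function() {
  g <- frequency_grid()
  g[3:(length(g) - 2)]
}
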