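# Minimal RIFF WAV reader/writer: mono, PCM16/24 and float32.

#' Read a mono WAV file
#'
#' Supports uncompressed PCM (16 or 24 bit) and IEEE float32, mono.
#' Integer samples are scaled to `[-1, 1)`.
#'
#' @param path Path to a WAV file.
#' @return A list with `samples` (numeric vector), `sample_rate_hz`,
#'   `bit_depth` and `format` (`"pcm"` or `"float"`).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt chunk")
      if (fmt$n_channels != 1) {
        stop("only mono WAV files are supported (found ",
             fmt$n_channels, " channels)")
      }
      n <- size %/% (fmt$bits %/% 8)
      if (fmt$audio_format == 3 && fmt$bits == 32) {
        samples <- readBin(con, "double", n, 4, endian = "little")
      } else if (fmt$audio_format == 1 && fmt$bits == 16) {
        samples <- readBin(con, "integer", n, 2, signed = TRUE,
                           endian = "little") / 32768
      } else if (fmt$audio_format == 1 && fmt$bits == 24) {
        raw <- readBin(con, "raw", n * 3)
        b <- matrix(as.integer(raw), nrow = 3)
        v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
        v <- ifelse(v >= 2^23, v - 2^24, v)
        samples <- v / 2^23
      } else {
        stop("unsupported WAV format (code ", fmt$audio_format, ", ",
             fmt$bits, " bit)")
      }
    } else {
      readBin(con, "raw", size + size %% 2)  # skip (chunks are word-aligned)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, sample_rate_hz = fmt$sample_rate,
       bit_depth = fmt$bits,
       format = if (fmt$audio_format == 3) "float" else "pcm")
}

#' Write a mono WAV file
#'
#' @param samples Numeric vector of samples (nominal range `[-1, 1]`).
#' @param path Output path.
#' @param sample_rate_hz Sample rate in Hz.
#' @param bit_depth `"float32"` (default), `"pcm16"` or `"pcm24"`.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(samples, path, sample_rate_hz,
                      bit_depth = c("float32", "pcm16", "pcm24")) {
  bit_depth <- match.arg(bit_depth)
  n <- length(samples)
  bytes <- switch(bit_depth, float32 = 4L, pcm16 = 2L, pcm24 = 3L)
  fmt_code <- if (bit_depth == "float32") 3L else 1L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes), con, 4, endian = "little")
  writeBin(bytes, con, 2, endian = "little")              # block align
  writeBin(8L * bytes, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == "float32") {
    writeBin(samples, con, 4, endian = "little")
  } else if (bit_depth == "pcm16") {
    v <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
    writeBin(v, con, 2, endian = "little")
  } else {
    v <- pmax(-2^23, pmin(2^23 - 1, round(samples * 2^23)))
    v <- ifelse(v < 0, v + 2^24, v)
    raw <- as.raw(rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536))
    writeBin(as.vector(raw), con)
  }
  invisible(path)
}
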