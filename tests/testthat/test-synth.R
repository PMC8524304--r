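test_that("pure tones are calibrated", {
  x <- pure_tone(1000, 120, 0.1, 48000)
  expect_equal(max(abs(x)), 1, tolerance = 1e-6)
  expect_equal(signal_level_db_spl(x), 120, tolerance = 0.1)
  x65 <- pure_tone(500, 65, 0.2, 48000)
  expect_equal(signal_level_db_spl(x65), 65, tolerance = 0.1)
  # a 20 dB level drop scales amplitude by 0.1
  x45 <- pure_tone(500, 45, 0.2, 48000)
  expect_equal(max(abs(x45)) / max(abs(x65)), 0.1, tolerance = 1e-6)
  expect_error(pure_tone(30000, 65, 0.1, 48000), "Nyquist")
})

test_that("speech-shaped noise is calibrated, stationary and seed-stable", {
  x <- speech_shaped_noise(70, 2, 5, 32000)
  expect_equal(signal_level_db_spl(x), 70, tolerance = 0.2)
  expect_identical(x, speech_shaped_noise(70, 2, 5, 32000))
  y <- speech_shaped_noise(70, 2, 6, 32000)
  expect_lt(abs(cor(x, y)), 0.05)
  # stationarity: SD of 125 ms window levels below 3 dB
  n <- round(0.125 * 32000)
  wlev <- vapply(seq(1, length(x) - n, n), function(i) {
    signal_level_db_spl(x[i:(i + n - 1)])
  }, numeric(1))
  expect_lt(sd(wlev), 3)
})

test_that("speech-shaped noise follows the embedded spectrum shape", {
  fs <- 32000
  x <- speech_shaped_noise(70, 8, 7, fs)
  n <- length(x)
  P <- Mod(fft(x))[1:(n / 2)]^2
  f <- (0:(n / 2 - 1)) * fs / n
  edges <- 2^seq(log2(100), log2(10000), by = 1 / 3)
  lev <- vapply(seq_len(length(edges) - 1), function(i) {
    sel <- f >= edges[i] & f < edges[i + 1]
    10 * log10(mean(P[sel]))
  }, numeric(1))
  ctr <- sqrt(edges[-length(edges)] * edges[-1])
  target <- approx(log(platt:::.ltass_freq_hz), platt:::.ltass_db,
                   xout = log(ctr))$y
  dev <- (lev - target) - mean(lev - target)
  expect_lt(max(abs(dev)), 2)
})

test_that("fluctuating noise is co-modulated with bounded pauses", {
  fs <- 32000
  x <- fluctuating_noise(70, 4, 8, fs)
  expect_equal(signal_level_db_spl(x), 70, tolerance = 0.2)
  expect_identical(x, fluctuating_noise(70, 4, 8, fs))
  # envelope gap scan: no stretch below -15 dB of the median level
  # exceeds 250 ms
  env <- stats::filter(abs(x), rep(1 / 320, 320), sides = 2)
  env[is.na(env)] <- median(env, na.rm = TRUE)
  low <- env < median(env) * 10^(-15 / 20)
  runs <- rle(as.vector(low))
  max_gap_ms <- max(c(0, runs$lengths[runs$values])) / fs * 1000
  expect_lte(max_gap_ms, 250)
  # long-term spectrum close to the stationary generator's
  ssn <- speech_shaped_noise(70, 4, 8, fs)
  spec_oct <- function(s) {
    n <- length(s)
    P <- Mod(fft(s))[1:(n / 2)]^2
    f <- (0:(n / 2 - 1)) * fs / n
    edges <- 2^seq(log2(125), log2(8000), by = 1)
    vapply(seq_len(length(edges) - 1), function(i) {
      10 * log10(mean(P[f >= edges[i] & f < edges[i + 1]]))
    }, numeric(1))
  }
  d <- spec_oct(x) - spec_oct(ssn)
  expect_lt(max(abs(d - mean(d))), 3)
})

test_that("fluctuating-noise envelope modulation peaks at syllabic rates", {
  fs <- 32000
  x <- fluctuating_noise(65, 8, 9, fs)
  env <- abs(x)
  # decimate the envelope to 100 Hz
  d <- fs / 100
  env100 <- vapply(seq(1, length(env) - d, d), function(i) {
    mean(env[i:(i + d - 1)])
  }, numeric(1))
  env100 <- env100 - mean(env100)
  P <- Mod(fft(env100))[1:(length(env100) / 2)]^2
  f <- (0:(length(env100) / 2 - 1)) * 100 / length(env100)
  pk <- f[f >= 0.5][which.max(P[f >= 0.5])]
  expect_gte(pk, 2)
  expect_lte(pk, 8)
})

test_that("the word corpus is labeled, jittered and separable", {
  corp <- synthetic_word_corpus(10, 20, seed = 3, sample_rate_hz = 32000)
  expect_length(corp$tokens, 200)
  words <- vapply(corp$tokens, `[[`, numeric(1), "word")
  expect_equal(as.vector(table(words)), rep(20, 10))
  # per-token calibration
  lv <- vapply(corp$tokens[1:10], function(t) {
    signal_level_db_spl(t$audio)
  }, numeric(1))
  expect_equal(lv, rep(65, 10), tolerance = 0.1)
  # determinism
  corp2 <- synthetic_word_corpus(10, 20, seed = 3, sample_rate_hz = 32000)
  expect_identical(corp$tokens[[7]]$audio, corp2$tokens[[7]]$audio)
  # separation in feature space: silhouette of pooled log-Mel statistics
  feats <- t(vapply(corp$tokens[1:100], function(t) {
    lms <- log_mel_spectrogram(t$audio, 32000)
    colMeans(lms$values_db)
  }, numeric(36)))
  w <- words[1:100]
  sil <- vapply(seq_len(nrow(feats)), function(i) {
    d <- sqrt(rowSums(sweep(feats, 2, feats[i, ])^2))
    a <- mean(d[w == w[i]][d[w == w[i]] > 0])
    b <- min(vapply(setdiff(unique(w), w[i]), function(v) {
      mean(d[w == v])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("SNR mixing scales speech relative to the masker level", {
  fs <- 32000
  sp <- pure_tone(1000, 80, 0.4, fs)
  mk <- speech_shaped_noise(70, 1, 10, fs)
  mix <- mix_at_snr(sp, mk, 0, 70, seed = 1)
  # at 0 dB SNR the speech component is scaled to 70 dB SPL: total is
  # 3 dB above the masker alone
  expect_equal(signal_level_db_spl(mix), 73, tolerance = 0.7)
  expect_identical(mix_at_snr(sp, mk, 0, 70, seed = 1), mix)
  expect_identical(mix_at_snr(sp, mk, Inf, 70), sp)
  expect_error(mix_at_snr(mk, sp, 0, 70), "shorter")
  expect_warning(mix_at_snr(sp, mk, 60, 70, seed = 1), "full scale")
})
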