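test_that("frequency grid matches the embedded design constants", {
  g <- frequency_grid()
  expect_length(g, 82)
  expect_equal(g[1], 64)
  expect_equal(g[82], 15080)
  expect_equal(g[41], 2708)
  expect_true(all(diff(g) > 0))
  cf <- channel_freqs()
  expect_length(cf, 78)
  expect_equal(cf[1], 123)
  expect_equal(cf[78], 13943)
})

test_that("bandwidth rule and channel invariants hold", {
  fb <- fb48()
  g <- frequency_grid()
  # bandwidth = grid two positions right minus two positions left
  expect_equal(fb$bandwidth_10db_hz, g[5:82] - g[1:78])
  expect_equal(fb$bandwidth_10db_hz[fb$center_freq_hz == 155], 128)
  # stability and pole phase
  expect_true(all(Mod(fb$pole) > 0 & Mod(fb$pole) < 1))
  expect_equal(Arg(fb$pole), 2 * pi * fb$center_freq_hz / 48000,
               tolerance = 1e-9)
})

test_that("designed channels meet peak gain 2 and the -10 dB points", {
  fb <- fb48()
  for (k in c(1, 17, 39, 60, 78)) {
    fc <- fb$center_freq_hz[k]
    bw <- fb$bandwidth_10db_hz[k]
    H <- function(f) Mod(fb$fir_coeff[k]) *
      (1 / Mod(1 - fb$pole[k] * exp(-2i * pi * f / 48000)))^4
    f_dense <- seq(max(1, fc - 2 * bw), min(23999, fc + 2 * bw), by = 0.5)
    pk <- max(H(f_dense))
    expect_equal(pk, 2, tolerance = 0.01)
    # -10 dB at fc +- bw/2 within 2 % of the bandwidth: compare the
    # measured -10 dB points to the nominal ones
    fpk <- f_dense[which.max(H(f_dense))]
    lo <- uniroot(function(f) H(f) - pk * 10^(-0.5), c(1, fpk))$root
    hi <- uniroot(function(f) H(f) - pk * 10^(-0.5), c(fpk, 23999))$root
    expect_lt(abs((hi - lo) - bw), 0.02 * bw)
    expect_lt(abs(lo - (fc - bw / 2)), 0.02 * bw + abs(fpk - fc))
  }
})

test_that("filterbank is stable across 32-96 kHz sample rates", {
  for (fs in c(32000, 96000)) {
    fb <- design_filterbank(fs)
    expect_true(all(Mod(fb$pole) < 1))
    expect_true(all(Mod(fb$pole) > 0))
  }
  expect_error(design_filterbank(16000), "sample_rate_hz")
})

test_that("analysis equals direct convolution with the analytic impulse response", {
  fb <- fb48()
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  bands <- fb_analyze(x, fb)
  nh <- round(0.05 * 48000)
  for (k in c(5, 40, 70)) {
    h <- gt_impulse_oracle(fb, k, nh)
    ref <- vapply(seq_len(n), function(t) {
      m <- min(t, nh)
      sum(h[1:m] * x[t - (0:(m - 1))])
    }, complex(1))
    expect_lt(max(Mod(bands[k, ] - ref)) / max(Mod(ref)), 1e-6)
  }
})

test_that("analysis preserves tone amplitude at channel center", {
  fb <- fb48()
  x <- pure_tone(1039, 65, 0.3, 48000)
  k <- which(fb$center_freq_hz == 1039)
  steady <- Mod(fb_analyze(x, fb)[k, 7000:14000])
  expect_equal(mean(steady), 10^((65 - 120) / 20), tolerance = 0.05)
})

test_that("degenerate analysis inputs are handled", {
  fb <- fb48()
  expect_equal(dim(fb_analyze(numeric(0), fb)), c(78L, 0L))
  z <- fb_analyze(rep(0, 500), fb)
  expect_true(all(Mod(z) == 0))
  expect_error(fb_analyze(c(1, NA), fb), "finite")
})

test_that("joint response is flat and sweeps downward", {
  fb <- fb48()
  jr <- joint_response(fb)
  band <- jr$freq_hz >= 200 & jr$freq_hz <= 12000
  ripple <- max(jr$magnitude_db[band]) - min(jr$magnitude_db[band])
  expect_lt(ripple, 3)
  # normalized passband sits at 0 dB
  expect_lt(abs(mean(jr$magnitude_db[band])), 0.5)
  # group delay decreases with center frequency (downward sweep)
  expect_true(all(diff(jr$delay_ms) < 0))
  expect_true(all(diff(jr$delay_peak_ms) <= 0))
})

test_that("resynthesis with 0 dB gains is transparent within ripple", {
  fb <- fb48()
  x <- speech_shaped_noise(65, 0.4, 3, 48000)
  y <- fb_resynthesize(fb_analyze(x, fb), NULL, fb)
  expect_length(y, length(x))
  # compare third-octave-smoothed magnitude spectra over the passband
  n <- length(x)
  fx <- Mod(fft(x))[1:(n / 2)]
  fy <- Mod(fft(y))[1:(n / 2)]
  f <- (0:(n / 2 - 1)) * 48000 / n
  edges <- 2^seq(log2(250), log2(10000), by = 1 / 3)
  ratio_db <- vapply(seq_len(length(edges) - 1), function(i) {
    sel <- f >= edges[i] & f < edges[i + 1]
    10 * log10(sum(fy[sel]^2) / sum(fx[sel]^2))
  }, numeric(1))
  expect_lt(max(abs(ratio_db)), 1)
})

test_that("static gain scales a tone accordingly (linearity)", {
  fb <- fb48()
  x <- pure_tone(1039, 65, 0.2, 48000)
  bands <- fb_analyze(x, fb)
  gains <- matrix(20 * log10(2), 78, 200)
  y0 <- fb_resynthesize(bands, NULL, fb)
  y1 <- fb_resynthesize(bands, gains, fb)
  s <- 6000:9000
  expect_equal(sqrt(mean(y1[s]^2)) / sqrt(mean(y0[s]^2)), 2,
               tolerance = 0.01)
  expect_error(fb_resynthesize(bands, gains[1:10, ], fb), "channels")
})

test_that("slew limiter caps the applied gain rate per period", {
  fb <- fb48()
  nf <- 50
  gains <- matrix(0, 78, nf)
  gains[, 11:nf] <- 24
  ag <- applied_gain(gains, 48000 * nf / 1000, fb)
  for (k in c(3, 22, 50, 78)) {
    fc <- fb$center_freq_hz[k]
    period <- floor(48000 / fc)
    g <- ag[k, ]
    worst <- max(abs(g[(1 + period):length(g)] -
                       g[1:(length(g) - period)]))
    expect_lte(worst, 24 + 1e-9)
    # the full 24 dB step is not reached earlier than one period after
    # the gain starts moving
    moved <- which(g > 1e-12)[1]
    reached <- which(g >= 24 - 1e-9)[1]
    expect_gte(reached - moved + 1, floor(48000 / fc))
  }
})
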