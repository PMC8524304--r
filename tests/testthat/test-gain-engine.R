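test_that("smoothing matches the direct convolution oracle", {
  set.seed(11)
  x <- rnorm(78, 60, 10)
  for (w in c(8, 16, 32, 64)) {
    expect_equal(smooth_spectrum(x, w), smooth_oracle(x, w),
                 tolerance = 1e-12)
  }
  # constant vector is unchanged (unit-sum window, reflection padding)
  expect_equal(smooth_spectrum(rep(5, 78), 8), rep(5, 78))
  # interior unit impulse reproduces the kernel
  imp <- numeric(78)
  imp[40] <- 1
  expect_equal(smooth_spectrum(imp, 8), smooth_oracle(imp, 8))
  # width-8 kernel has a FWHM of about 4 samples (2 ERB)
  k <- smooth_spectrum(imp, 8)
  above <- which(k >= max(k) / 2)
  expect_equal(length(above), 4, tolerance = 1)
})

test_that("layer decomposition reconstructs exactly and matrix path agrees", {
  set.seed(12)
  x <- rnorm(78, 60, 8)
  ld <- decompose_layers(x)
  expect_lt(max(abs(ld$base + ld$d4 + ld$d3 + ld$d2 + ld$d1 - x)), 1e-9)
  M <- matrix(rnorm(5 * 78, 60, 8), 5, 78)
  lm <- platt:::.decompose_layers_mat(M)
  for (r in 1:5) {
    ld_r <- decompose_layers(M[r, ])
    expect_equal(lm$d2[r, ], ld_r$d2, tolerance = 1e-12)
    expect_equal(lm$base[r, ], ld_r$base, tolerance = 1e-12)
  }
})

test_that("two-tone frame keeps the layer dynamics within the design bounds", {
  fb <- fb48()
  d1_max <- 0
  d2_max <- 0
  for (L in seq(40, 105, 13)) {
    ld <- decompose_layers(two_tone_frame(fb, L))
    d1_max <- max(d1_max, max(abs(ld$d1)))
    d2_max <- max(d2_max, max(abs(ld$d2)))
  }
  # the dynamic encoded in difference 2 stays below 9 dB, difference 1
  # around 6 dB
  expect_lt(d2_max, 9)
  expect_equal(d1_max, 6, tolerance = 2)
})

test_that("base layer mapping is affine with the documented endpoints", {
  drs <- dynamic_range_spec(c(500, 1000, 2000), in_low = 25, in_high = 105,
                            out_low = 50, out_high = 90)
  expect_equal(map_base_layer(c(25, 65, 105), drs, "linear"),
               c(50, 70, 90))
  expect_equal(map_base_layer(c(10, 70, 120), drs, "identity"),
               c(10, 70, 120))
  expect_error(dynamic_range_spec(1000, in_low = 50, in_high = 40),
               "low < high")
})

test_that("conditional factor matches its worked example and a brute force", {
  drs <- dynamic_range_spec(1000, in_low = 25, in_high = 105,
                            out_low = 50, out_high = 90)
  expect_equal(conditional_factor(80, 30, drs), 1 / 3)
  expect_equal(conditional_factor(60, -30, drs), 1 / 3)
  expect_equal(conditional_factor(70, 0, drs), 1)
  # brute force over an alpha grid: largest alpha keeping the result in
  # range
  set.seed(13)
  alphas <- seq(0, 1, 1e-4)
  for (i in 1:50) {
    cur <- runif(1, 30, 110)
    d <- runif(1, -40, 40)
    got <- conditional_factor(cur, d, drs)
    ok <- alphas[cur + alphas * d >= 50 - 1e-9 &
                   cur + alphas * d <= 90 + 1e-9]
    ref <- if (length(ok) == 0) 0 else max(ok)
    # out-of-range current values moving inward are allowed factor 1
    if (cur < 50 && d > 0) ref <- max(ref, min(1, (90 - cur) / d))
    if (cur > 90 && d < 0) ref <- max(ref, min(1, (50 - cur) / d))
    expect_lt(abs(got - ref), 2e-4)
  }
})

test_that("factor propagation reproduces the printed caps and the oracle", {
  cf <- channel_freqs()
  raw <- rep(1, 78)
  raw[cf == 2708] <- 0
  f <- propagate_factors(raw, fwhm = 6)
  expect_lte(f[cf == 2346], 0.5)
  expect_lte(f[cf == 3112], 0.5)
  expect_equal(f[cf == 2346], 0.5)
  expect_equal(f[cf == 3112], 0.5)
  expect_true(all(f[cf <= 2023] == 1))
  expect_true(all(f[cf >= 3565] == 1))
  # all-ones raw passes through
  expect_equal(propagate_factors(rep(1, 78), 6), rep(1, 78))
  # random vectors match the exhaustive oracle; output never exceeds raw
  set.seed(14)
  for (fwhm in c(6, 12)) {
    r <- runif(78)
    got <- propagate_factors(r, fwhm)
    expect_equal(got, propagate_oracle(r, fwhm), tolerance = 1e-12)
    expect_true(all(got <= r + 1e-12))
  }
})

test_that("pass-through configurations give zero gain", {
  set.seed(15)
  cf <- channel_freqs()
  # identity map, factor 1, unbounded output range: exactly zero
  drs_inf <- dynamic_range_spec(cf, in_low = -1e6, in_high = 1e6,
                                out_low = -1e6, out_high = 1e6)
  frame <- rnorm(78, 60, 8)
  g <- compute_frame_gain(frame, drs_inf,
                          expansion_config(1, "identity"))
  expect_lt(max(abs(g)), 1e-9)
  # out range equal to in range, frame strictly inside: near zero
  drs <- dynamic_range_spec(cf)
  frame_in <- pmin(100, pmax(35, rnorm(78, 65, 5)))
  g2 <- compute_frame_gain(frame_in, drs, expansion_config(1, "linear"))
  expect_lt(max(abs(g2)), 1e-9)
})

test_that("conditional additions never push an in-range channel outside", {
  set.seed(16)
  cf <- channel_freqs()
  drs <- dynamic_range_spec(cf, out_low = 50, out_high = 90)
  for (i in 1:20) {
    cur <- runif(78, 50, 90)
    d <- rnorm(78, 0, 15)
    f <- conditional_factor(cur, d, drs)
    out <- cur + f * d
    expect_true(all(out >= 50 - 1e-9 & out <= 90 + 1e-9))
    # propagation only lowers factors, so it cannot re-violate limits
    fp <- propagate_factors(f, 6)
    expect_true(all(fp <= f + 1e-12))
  }
})

test_that("expansion acts only on difference 2 and scales linearly", {
  fb <- fb48()
  cf <- channel_freqs()
  drs_inf <- dynamic_range_spec(cf, in_low = -1e6, in_high = 1e6,
                                out_low = -1e6, out_high = 1e6)
  frame <- two_tone_frame(fb, 65)
  ld <- decompose_layers(frame)
  g1 <- compute_frame_gain(frame, drs_inf, expansion_config(1, "identity"))
  g2 <- compute_frame_gain(frame, drs_inf, expansion_config(2, "identity"))
  g4 <- compute_frame_gain(frame, drs_inf, expansion_config(4, "identity"))
  # with unbounded ranges the gain difference is exactly (E - 1) * d2
  expect_equal(g2 - g1, ld$d2, tolerance = 1e-9)
  expect_equal(g4 - g1, 3 * ld$d2, tolerance = 1e-9)
  # frames differing only in d3/d4 content get identical d2 contributions
  frame_b <- frame + smooth_spectrum(rnorm(78, 0, 6), 16) -
    smooth_spectrum(rnorm(78, 0, 6), 64)
  ld_b <- decompose_layers(frame_b)
  gb1 <- compute_frame_gain(frame_b, drs_inf,
                            expansion_config(1, "identity"))
  gb4 <- compute_frame_gain(frame_b, drs_inf,
                            expansion_config(4, "identity"))
  expect_equal(gb4 - gb1, 3 * ld_b$d2, tolerance = 1e-9)
})

test_that("low spectral dynamic in a reduced range is not compressed", {
  cf <- channel_freqs()
  drs <- dynamic_range_spec(cf, out_low = 50, out_high = 90)
  # white-noise-dominated frame: smooth, low spectral dynamic
  frame <- 65 + smooth_spectrum(rnorm(78, 0, 1.5), 32)
  g <- compute_frame_gain(frame, drs, expansion_config(1, "linear"))
  # gains nearly uniform across frequency (no per-channel compression)
  expect_lt(diff(range(g)), 3)
  # high spectral dynamic in the same range is compressed
  fb <- fb48()
  frame_hi <- two_tone_frame(fb, 95)
  g_hi <- compute_frame_gain(frame_hi, drs, expansion_config(1, "linear"))
  expect_gt(diff(range(g_hi)), 10)
})

test_that("full processing raises output level of noisy speech under expansion", {
  fs <- 32000
  corp <- synthetic_word_corpus(2, 1, seed = 31, sample_rate_hz = fs)
  sp <- corp$tokens[[1]]$audio
  masker <- speech_shaped_noise(65, 2, 32, fs)
  mix <- mix_at_snr(sp, masker, 0, 65, seed = 33)
  y8 <- platt_process(mix, fs, platt_config(expansion_factor = 8,
                                            base_map = "identity"))
  # direction only: strong expansion raises the broadband RMS level
  expect_gt(signal_level_db_spl(y8), signal_level_db_spl(mix))
  # d2 dynamic measured on the reprocessed output grows with the factor
  fb <- design_filterbank(fs)
  d2_of <- function(x) {
    et <- envelope_track(fb_analyze(x, fb), fb)
    fr <- et$levels_db_spl[round(nrow(et$levels_db_spl) / 2), ]
    diff(range(decompose_layers(fr)$d2))
  }
  y1 <- platt_process(mix, fs, platt_config(expansion_factor = 1,
                                            base_map = "identity"))
  y4 <- platt_process(mix, fs, platt_config(expansion_factor = 4,
                                            base_map = "identity"))
  d2s <- c(d2_of(y1), d2_of(y4), d2_of(y8))
  expect_true(all(diff(d2s) > 0))
})
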