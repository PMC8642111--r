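test_that("ERB formula and scale behave as designed", {
  expect_equal(erb_bandwidth(1000), 132.64, tolerance = 1e-4)
  expect_equal(erb_bandwidth(80), 33.34, tolerance = 1e-3)
  expect_lt(abs(erb_bandwidth(1e-6) - 24.7), 1e-3)  # low-frequency limit
  expect_error(erb_bandwidth(0), "positive")
  # ERB-number scale is the integral of 1/ERB: inverse round-trips
  f <- c(80, 500, 1000, 4000, 10000)
  expect_equal(erb_number_inverse(erb_number(f)), f)
})

test_that("filterbank spans 80 Hz-10 kHz at one-ERB spacing with 33 channels", {
  nh <- design_filterbank(22050, 1)
  expect_length(nh$cf, 33)
  expect_equal(nh$cf[1], 80, tolerance = 1e-6)
  expect_true(all(nh$cf <= 10000))
  expect_equal(diff(erb_number(nh$cf)), rep(1, 32), tolerance = 1e-9)
  expect_error(design_filterbank(16000, 1), "Nyquist")
})

test_that("realized filter bandwidths match the design scale", {
  nh <- design_filterbank(22050, 1)
  hi <- design_filterbank(22050, 2)
  for (ch in c(5, 15, 25, 33)) {
    ratio_hi <- realized_erb(hi, ch) / erb_bandwidth(hi$cf[ch])
    ratio_nh <- realized_erb(nh, ch) / erb_bandwidth(nh$cf[ch])
    expect_equal(ratio_hi, 2, tolerance = 0.05)
    expect_equal(ratio_nh, 1, tolerance = 0.05)
  }
})

test_that("envelope/fine decomposition obeys the analytic-signal identities", {
  fs <- 8000
  t <- seq(0, 0.5, by = 1 / fs)
  x <- 0.7 * sin(2 * pi * 440 * t)
  d <- envelope_fine_decompose(x)
  core <- seq(400, length(x) - 400)
  expect_equal(mean(d$envelope[core]), 0.7, tolerance = 1e-3)
  expect_true(all(d$envelope >= 0))
  expect_true(all(abs(d$fine) <= 1 + 1e-12))
  expect_equal(d$envelope * d$fine, x, tolerance = 1e-9)
  # independent FFT oracle on a noise band, written out in full here
  set.seed(42)
  n <- 4096
  b <- as.numeric(stats::filter(rnorm(n), rep(1 / 8, 8), sides = 2))
  b[is.na(b)] <- 0
  b <- b - mean(b)
  X <- fft(b)
  h <- c(1, rep(2, n / 2 - 1), 1, rep(0, n / 2 - 1))
  oracle_env <- Mod(fft(X * h, inverse = TRUE) / n)
  expect_equal(envelope_fine_decompose(b)$envelope, oracle_env,
               tolerance = 1e-9)
})

test_that("imposing a signal's own normal envelopes is near-transparent", {
  x <- gen_speech_like_audio(duration = 1, seed = 5)
  y <- impose_impaired_envelopes(x, n_iter = 1, bandwidth_scale = 1)
  expect_gt(envelope_correlation(y, x, bandwidth_scale = 1), 0.995)
})

test_that("silent input is returned unchanged with a warning", {
  x <- audio_signal(numeric(4410), 22050, ref_rms = 1)
  expect_warning(y <- impose_impaired_envelopes(x), "silent")
  expect_identical(y$samples, x$samples)
})

test_that("envelope correlation scores and guards behave", {
  x <- gen_speech_like_audio(duration = 1, seed = 1)
  z <- gen_speech_like_audio(duration = 1, seed = 2)
  # a signal against its own targets, processed vs unprocessed
  expect_gt(envelope_correlation(x, x), 0.85)
  # independent noise decorrelates (envelopes share only slow statistics)
  expect_lt(envelope_correlation(z, x), 0.5)
  expect_error(envelope_correlation(
    audio_signal(numeric(1000) + 1e-9, 22050, ref_rms = 1),
    audio_signal(numeric(1000) + 1e-9, 22050, ref_rms = 1)),
    "no informative bands")
  expect_error(
    envelope_correlation(x, gen_speech_like_audio(duration = 1.5, seed = 1)),
    "lengths differ")
})

test_that("iteration does not hurt envelope delivery on average", {
  diffs <- vapply(1:20, function(s) {
    x <- gen_speech_like_audio(duration = 1, seed = s)
    tr <- attr(impose_impaired_envelopes(x, n_iter = 10, trace = TRUE),
               "correlation_trace")
    tr[10] - tr[1]
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("RMS equalization is exact and shape-preserving", {
  ref <- gen_speech_like_audio(duration = 1, seed = 3)
  y <- audio_signal(ref$samples * 0.5, ref$rate)
  eq <- rms_equalize(y, ref)
  expect_equal(eq$samples, ref$samples)          # scaled by exactly 2
  expect_identical(rms_equalize(ref, ref)$samples, ref$samples)
  z <- audio_signal(rnorm(1000), 22050)
  err_db <- 20 * log10(rms(rms_equalize(z, ref)) / rms(ref))
  expect_lt(abs(err_db), 0.01)
  expect_error(rms_equalize(audio_signal(numeric(10), 22050, ref_rms = 1),
                            ref), "silence")
})

test_that("loudness mapping is monotone, expansive, and attenuation-only", {
  lf <- loudness_functions()
  levels <- seq(-10, 110, by = 1)
  for (b in 1:6) {
    out <- loudness_map_level(levels, b, lf)
    expect_true(all(diff(out) >= 0))             # monotone
    expect_true(all(out <= levels + 1e-12))      # never amplifies
  }
  # expansion: slope above threshold exceeds 1 (recruitment)
  sweep <- loudness_map_level(seq(46, 96, by = 5), 3, lf)  # 1 kHz, thr 45
  expect_true(all(diff(sweep) / 5 > 1))
  # both loudness curves meet at the anchor: no gain at high level
  expect_equal(loudness_map_level(105, 6, lf), 105)
  # impaired curve reaches 0 CU exactly at the band threshold
  expect_equal(lf$hi_cu(lf$hi_thr[4], 4), 0)
  expect_gt(lf$hi_cu(lf$hi_thr[4] + 1, 4), 0)
})

test_that("sub-threshold bands emerge below normal audibility", {
  lf <- loudness_functions()
  ag <- audiogram_n3()
  for (b in 1:6) {
    below <- ag$threshold_hl[b] - 5
    out <- loudness_map_level(below, b, lf)
    expect_lt(out, lf$nh_thr[b])
    expect_equal(lf$nh_cu(out, b), 0)
  }
  # end to end: 500 Hz tone at 30 dB HL (simulated threshold 40) inaudible
  y <- loudness_transform(pure_tone(500, 30, duration = 0.25))
  expect_equal(loudness_functions()$nh_cu(band_level(y, 2), 2), 0)
})

test_that("loudness transform validates calibration and reconstructs levels", {
  x <- pure_tone(1000, 80, duration = 0.25)
  y <- loudness_transform(x)
  # 80 dB at 1 kHz (threshold 45): target level from the recruitment map
  expect_lt(abs(band_level(y, 3) -
                  loudness_map_level(80, 3, loudness_functions())), 0.3)
  bad <- x
  bad$calibration_spl <- NA_real_
  expect_error(loudness_transform(bad), "calibrated")
})

test_that("full impairment simulation preserves RMS and is deterministic", {
  x <- gen_speech_like_audio(duration = 1, seed = 8)
  y1 <- simulate_hearing_impairment(x, n_iter = 2)
  y2 <- simulate_hearing_impairment(x, n_iter = 2)
  expect_identical(y1$samples, y2$samples)       # bit-identical, no RNG
  expect_lt(abs(20 * log10(rms(y1) / rms(x))), 0.01)
  expect_false(isTRUE(all.equal(y1$samples, x$samples)))
})

test_that("audiogram validates its ranges", {
  expect_error(audiogram(thresholds_hl = c(0, 0, 0, 0, 0, 130)), "120")
  expect_error(audiogram(freqs = c(250, 500), thresholds_hl = 1), "length")
  expect_equal(audiogram_n3()$threshold_hl, c(40, 40, 45, 54, 62, 70))
})
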