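test_that("amplitude map matches the mean-absolute-deviation definition", {
  # constant video: zero deviation everywhere
  vconst <- video_cube(array(5, c(8, 3, 3)), 32)
  expect_true(all(compute_amplitude_map(vconst) == 0))

  # alternating 10,12,10,12 with N = 4: mean 11, MAD exactly 1
  v <- array(5, c(4, 2, 2))
  v[, 1, 1] <- c(10, 12, 10, 12)
  am <- compute_amplitude_map(video_cube(v, 32), window = 4)
  expect_equal(am[1, 1], 1)
  expect_equal(am[2, 2], 0)

  # random cube equals the naive triple-loop oracle, single and multi window
  withr::with_seed(2, {
    vr <- video_cube(array(rnorm(64 * 8 * 8, 100, 5), c(64, 8, 8)), 32)
  })
  for (win in c(64, 16)) {
    expect_equal(unclass(compute_amplitude_map(vr, window = win)),
                 naive_amplitude_map(vr, win), ignore_attr = TRUE)
  }
  expect_error(compute_amplitude_map(vr, window = 1), "at least 2")
  expect_error(compute_amplitude_map(vr, window = 100), "exceeds")
})

test_that("frequency map finds injected tones and flags undefined pixels", {
  v <- make_tone_video(2, secs = 10, noise_sd = 0.05, seed = 9)
  fm <- compute_frequency_map(v)
  mask <- central_mask(8, 8)
  bin <- attr(v, "frame_rate") / attr(fm, "stft_window")
  expect_true(all(abs(fm[mask] - 2) <= bin + 1e-9))

  # constant series has no in-band power: undefined sentinel
  vconst <- video_cube(array(7, c(64, 4, 4)), 32)
  expect_true(all(is.na(compute_frequency_map(vconst))))

  # 1 Hz (amplitude 2) + 5 Hz (amplitude 1): the stronger tone wins
  tt <- 320; ts <- (0:(tt - 1)) / 32
  sig <- 2 * sin(2 * pi * 1 * ts) + 1 * sin(2 * pi * 5 * ts + 0.4)
  v2 <- video_cube(array(rep(100 + sig, 4), c(tt, 2, 2)), 32)
  fm2 <- compute_frequency_map(v2)
  expect_true(all(abs(fm2 - 1) <= 32 / attr(fm2, "stft_window") + 1e-9))

  expect_error(compute_frequency_map(v, band = c(0.01, 0.02)), "no STFT bin")
  expect_error(compute_frequency_map(v, band = c(1, 20)), "Nyquist")
})

test_that("region statistics match direct formulas and histogram entropy", {
  uni <- matrix(3.5, 6, 6)
  rs <- region_statistics(uni)
  expect_equal(rs$mean, 3.5)
  expect_equal(rs$variance, 0)
  expect_equal(rs$entropy_bits, 0)

  # two equally filled bins carry exactly one bit
  half <- matrix(c(rep(1, 18), rep(2, 18)), 6, 6)
  expect_equal(region_statistics(half, n_bins = 2)$entropy_bits, 1)

  withr::with_seed(5, { m <- matrix(runif(400), 20, 20) })
  rs2 <- region_statistics(m, n_bins = 16)
  expect_equal(rs2$entropy_bits, naive_hist_entropy_bits(as.numeric(m), 16))
  expect_equal(rs2$variance, mean((m - mean(m))^2))

  expect_error(region_statistics(uni, region = matrix(FALSE, 6, 6)), "empty")
  allna <- matrix(NA_real_, 2, 2)
  expect_error(region_statistics(allna), "undefined")
})

test_that("spectral features separate tones from broadband noise", {
  fs <- 32; tt <- 320; ts <- (0:(tt - 1)) / fs
  tone_low <- 100 + sin(2 * pi * 0.5 * ts)
  sf <- spectral_features(tone_low, fs, low_cut = 1)
  expect_equal(sf$low_freq_energy_ratio, 1, tolerance = 1e-6)
  expect_lte(sf$spectral_entropy, 0.05)

  tone_high <- 100 + sin(2 * pi * 5 * ts)
  expect_lt(spectral_features(tone_high, fs, low_cut = 1)$low_freq_energy_ratio,
            0.01)

  ents <- vapply(1:50, function(s) {
    withr::with_seed(s, spectral_features(rnorm(tt), fs)$spectral_entropy)
  }, numeric(1))
  expect_gte(mean(ents), 0.9)

  expect_error(spectral_features(rep(1, tt), fs), "zero in-band")
  expect_error(spectral_features(tone_low, fs, low_cut = 20), "inside")
})

test_that("maps are scale-equivariant and shift-invariant", {
  withr::with_seed(8, {
    v <- array(rnorm(64 * 6 * 6, 50, 3), c(64, 6, 6))
  })
  v1 <- video_cube(v, 32)
  vk <- video_cube(v * 2.5, 32)
  vs <- video_cube(v + 17, 32)
  expect_equal(unclass(compute_amplitude_map(vk)),
               2.5 * unclass(compute_amplitude_map(v1)))
  expect_equal(unclass(compute_amplitude_map(vs)),
               unclass(compute_amplitude_map(v1)))
  expect_equal(unclass(compute_frequency_map(vk)),
               unclass(compute_frequency_map(v1)))
  expect_equal(unclass(compute_frequency_map(vs)),
               unclass(compute_frequency_map(v1)))
})

test_that("vectorized maps equal naive loop oracles on a 16x16x128 cube", {
  withr::with_seed(13, {
    base <- array(rnorm(128 * 16 * 16, 100, 2), c(128, 16, 16))
  })
  ts <- (0:127) / 32
  for (r in 1:16) base[, r, 3] <- base[, r, 3] + 3 * sin(2 * pi * 2 * ts + r)
  v <- video_cube(base, 32)
  expect_equal(unclass(compute_amplitude_map(v, window = 32)),
               naive_amplitude_map(v, 32), ignore_attr = TRUE)
  fm <- compute_frequency_map(v, stft_window = 64, stft_overlap = 0.5)
  expect_equal(unclass(fm),
               naive_frequency_map(v, c(0.1, 10), 64, 0.5),
               ignore_attr = TRUE)
})
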