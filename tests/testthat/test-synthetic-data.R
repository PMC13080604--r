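test_that("video generation honours the component model and determinism", {
  # no components, no noise: every frame identical to the baseline
  sp0 <- vibration_spec(duration = 1, image_size = c(4, 4), components = list(),
                        noise_sd = 0)
  v0 <- generate_video(sp0, seed = 1)
  expect_true(all(v0 == v0[1, 1, 1]))

  # a pure 2 Hz tone dominates every masked pixel's periodogram within a bin
  v <- make_tone_video(2, secs = 10, noise_sd = 0.1, seed = 4)
  mask <- central_mask(8, 8)
  fs <- 32; tt <- dim(v)[1]
  freqs <- (0:(tt - 1)) * fs / tt
  for (px in which(mask)[c(1, 5, 9)]) {
    r <- (px - 1) %% 8 + 1; cc <- (px - 1) %/% 8 + 1
    s <- v[, r, cc]
    sp <- abs(fft(s - mean(s)))[2:(tt %/% 2)]
    f_hat <- freqs[1 + which.max(sp)]
    expect_lt(abs(f_hat - 2), fs / tt + 1e-9)
  }

  # seeded reproducibility is bit-exact
  spec <- vibration_spec(duration = 2, image_size = c(6, 6),
                         components = list(list(frequency_hz = 3,
                                                amplitude_um = 200)))
  expect_identical(generate_video(spec, seed = 7), generate_video(spec, seed = 7))
  expect_false(identical(generate_video(spec, seed = 7),
                         generate_video(spec, seed = 8)))
})

test_that("frequencies at or above Nyquist are rejected", {
  expect_error(vibration_spec(frame_rate = 32,
                              components = list(list(frequency_hz = 16,
                                                     amplitude_um = 10))),
               "Nyquist")
  expect_error(vibration_spec(components = list(list(frequency_hz = 2,
                                                     amplitude_um = -1))),
               "amplitude")
})

test_that("cohort tables carry exact fixed-count prevalences", {
  co <- generate_cohort(seed = 3)
  expect_equal(nrow(co), 98)
  expect_equal(sum(co$dep_severity >= 3), 73)
  expect_equal(sum(co$anx_severity >= 3), 52)
  expect_true(all(co$dep_severity %in% 1:5))
  expect_true(all(as.matrix(co[paste0("sds_item_", 1:20)]) %in% 1:4))
  # determinism
  expect_identical(co, generate_cohort(seed = 3))
  expect_error(generate_cohort(n_subjects = 10, n_dep_positive = 11),
               "exceed")
})

test_that("a zero AI effect size yields chance-level discrimination", {
  aucs <- vapply(1:20, function(s) {
    co <- generate_cohort(n_subjects = 98, ai_effect_size = 0, seed = s)
    roc_auc(co$ai_p_dep, co$dep_severity >= 3)$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("the scale-item composer hits requested raw scores exactly", {
  def <- scale_definition("sds")
  withr::with_seed(11, {
    for (raw in c(20, 35, 58, 80)) {
      items <- vibroscreen:::compose_scale_items(raw, def)
      expect_equal(score_scale(items, def)$raw, raw)
    }
  })
})

test_that("study fixtures reproduce the reconstructed confusion matrices", {
  fx <- study_fixtures()
  expect_equal(nrow(fx), 6)
  expect_true(all(fx$tp + fx$fp + fx$fn + fx$tn == 98))
  dep <- fx[fx$axis == "dep", ]
  expect_true(all(dep$tp + dep$fn == 73))
  anx <- fx[fx$axis == "anx", ]
  expect_true(all(anx$tp + anx$fn == 52))
  ai_dep <- fx[fx$axis == "dep" & fx$instrument == "ai", ]
  expect_equal(c(ai_dep$tp, ai_dep$fp, ai_dep$fn, ai_dep$tn), c(70, 24, 3, 1))
  # combined anxiety hits = scale hits plus the AI-unique detections
  expect_equal(fx$tp[fx$axis == "anx" & fx$instrument == "combined"],
               fx$tp[fx$axis == "anx" & fx$instrument == "scale"] +
                 fx$unique_detections[fx$axis == "anx" & fx$instrument == "ai"])
})

test_that("video cohorts enrich low-frequency energy in depression cases", {
  # one-sided separation of the spectral feature across seeded replicates
  case_means <- numeric(20); ctrl_means <- numeric(20)
  for (s in 1:20) {
    vc <- generate_video_cohort(n = 6, frames = 64, image_size = c(16, 16),
                                seed = s)
    ratios <- vapply(vc$videos, function(v)
      spectral_features(region_series(v, central_mask(16, 16, 0.75)),
                        frame_rate(v), low_cut = 2)$low_freq_energy_ratio,
      numeric(1))
    case_means[s] <- mean(ratios[vc$labels$y_dep == 1])
    ctrl_means[s] <- mean(ratios[vc$labels$y_dep == 0])
  }
  expect_gt(mean(case_means), mean(ctrl_means))
})
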