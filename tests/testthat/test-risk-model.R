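# small helpers for constructing cubes and models at toy scale
toy_videos <- function(n, tt = 8, hw = 6, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    video_cube(array(rnorm(tt * hw * hw, 100), c(tt, hw, hw)), 32)))
}

test_that("encoder emits one feature vector per time slice, deterministically", {
  cfg <- tiny_model_config()
  v <- toy_videos(1, tt = 12)[[1]]             # 12 frames -> 3 slices of 4
  prep <- vibroscreen:::rm_prepare(list(v), cfg)
  params <- vibroscreen:::rm_init_params(cfg, prep$geom$in_dim, seed = 5)
  model <- structure(list(params = params, config = cfg), class = "risk_model")
  z <- encode_frames(v, model)
  expect_equal(dim(z), c(3, cfg$d))
  expect_identical(z, encode_frames(v, model))

  # zero conv/proj weights (and biases) kill the features
  p0 <- params
  p0$conv_w[] <- 0; p0$conv_b[] <- 0; p0$proj_w[] <- 0; p0$proj_b[] <- 0
  for (i in seq_along(p0$blocks)) {
    p0$blocks[[i]]$a_w[] <- 0; p0$blocks[[i]]$a_b[] <- 0
    p0$blocks[[i]]$b_w[] <- 0; p0$blocks[[i]]$b_b[] <- 0
  }
  z0 <- encode_frames(v, structure(list(params = p0, config = cfg),
                                   class = "risk_model"))
  expect_true(all(z0 == 0))

  # a clip smaller than the receptive field is rejected
  tiny <- video_cube(array(1, c(8, 2, 2)), 32)
  expect_error(vibroscreen:::rm_prepare(list(tiny), cfg), "receptive-field")
})

test_that("bidirectional aggregation matches hand-unrolled LSTM algebra", {
  m <- 3; d <- 4
  withr::with_seed(21, {
    dir_par <- function() list(w = matrix(rnorm(d * 4 * m, 0, 0.4), d, 4 * m),
                               u = matrix(rnorm(m * 4 * m, 0, 0.4), m, 4 * m),
                               b = rnorm(4 * m, 0, 0.2))
    lstm <- list(lstm_fwd = dir_par(), lstm_bwd = dir_par())
    z1 <- matrix(rnorm(d), 1, d)
  })
  # single step: both directions reduce to one cell step from the zero state
  h <- aggregate_sequence(z1, lstm)
  expect_length(h, 2 * m)
  expect_equal(h[1:m], lstm_step_oracle(z1, lstm$lstm_fwd$w, lstm$lstm_fwd$u,
                                        lstm$lstm_fwd$b, m))
  expect_equal(h[(m + 1):(2 * m)],
               lstm_step_oracle(z1, lstm$lstm_bwd$w, lstm$lstm_bwd$u,
                                lstm$lstm_bwd$b, m))

  # with shared direction weights, reversing the sequence swaps the halves
  shared <- list(lstm_fwd = lstm$lstm_fwd, lstm_bwd = lstm$lstm_fwd)
  withr::with_seed(22, { zz <- matrix(rnorm(5 * d), 5, d) })
  h1 <- aggregate_sequence(zz, shared)
  h2 <- aggregate_sequence(zz[5:1, ], shared)
  expect_equal(h1[1:m], h2[(m + 1):(2 * m)])
  expect_equal(h1[(m + 1):(2 * m)], h2[1:m])

  expect_error(aggregate_sequence(matrix(0, 2, d + 1), lstm), "dimension")
})

test_that("prediction heads implement sigmoid(w.h + b) exactly", {
  m <- 3
  withr::with_seed(31, {
    heads <- list(head_dep = list(w = rnorm(2 * m), b = 0.3),
                  head_anx = list(w = rnorm(2 * m), b = -0.2),
                  head_sev_dep = list(w = rnorm(2 * m), b = 0.5),
                  head_sev_anx = list(w = rnorm(2 * m), b = 0.5))
    h <- rnorm(2 * m)
  })
  rs <- predict_risk(h, heads)
  expect_equal(rs$p_dep, plogis(sum(heads$head_dep$w * h) + 0.3))
  expect_equal(rs$sev_dep, 1 + 4 * (sum(heads$head_sev_dep$w * h) + 0.5))

  # zero weights and biases: exactly chance probabilities
  zero <- lapply(heads, function(hd) list(w = hd$w * 0, b = 0))
  rs0 <- predict_risk(h, zero)
  expect_equal(rs0$p_dep, 0.5)
  expect_equal(rs0$p_anx, 0.5)

  # sigmoid monotonicity in the logit
  up <- heads; up$head_dep$b <- heads$head_dep$b + 1
  expect_gt(predict_risk(h, up)$p_dep, rs$p_dep)

  expect_error(predict_risk(c(h[-1], NaN), heads), "finite")
  # zeroing the anxiety head leaves the depression output untouched
  noanx <- heads; noanx$head_anx$w[] <- 0; noanx$head_anx$b <- 0
  expect_equal(predict_risk(h, noanx)$p_dep, rs$p_dep)
})

test_that("analytic gradients agree with central differences", {
  cfg <- tiny_model_config()
  vids <- toy_videos(3, tt = 8, seed = 41)
  prep <- vibroscreen:::rm_prepare(vids, cfg)
  params <- vibroscreen:::rm_init_params(cfg, prep$geom$in_dim, seed = 42)
  targets <- list(y_dep = c(1, 0, 1), y_anx = c(0, 1, 1),
                  t_sdep = c(0.8, 0.1, 0.5), t_sanx = c(0.2, 0.9, 0.6))
  lg <- vibroscreen:::rm_loss_grad(params, prep, targets, cfg)
  flat <- vibroscreen:::rm_flatten(params)
  gflat <- vibroscreen:::rm_flatten(lg$grads)
  eps <- 1e-6
  withr::with_seed(43, { idx <- sample(length(flat), 40) })
  for (j in idx) {
    fp <- flat; fp[j] <- fp[j] + eps
    fm <- flat; fm[j] <- fm[j] - eps
    lp <- vibroscreen:::rm_loss_grad(vibroscreen:::rm_unflatten(fp, params),
                                     prep, targets, cfg)$loss
    lm <- vibroscreen:::rm_loss_grad(vibroscreen:::rm_unflatten(fm, params),
                                     prep, targets, cfg)$loss
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(gflat[j] - num), 1e-6 + 1e-4 * abs(num))
  }
})

test_that("training is seeded, loss-reducing, and prediction is pure", {
  vc <- generate_video_cohort(n = 24, frames = 32, image_size = c(16, 16),
                              seed = 51)
  cfg <- risk_model_config(pool = 2, conv_channels = 2, d = 4, hidden = 4,
                           n_blocks = 1, epochs = 8, batch_size = 12)
  m1 <- train_risk_model(vc$videos, vc$labels, cfg, seed = 52)
  m2 <- train_risk_model(vc$videos, vc$labels, cfg, seed = 52)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$loss_history[1])

  p1 <- predict(m1, vc$videos[1:4])
  expect_identical(p1, predict(m1, vc$videos[1:4]))
  expect_true(all(p1$p_dep >= 0 & p1$p_dep <= 1))
  expect_true(all(p1$p_anx >= 0 & p1$p_anx <= 1))

  # zeroing the anxiety head cannot move the depression probabilities
  m3 <- m1
  m3$params$head_anx$w[] <- 0; m3$params$head_anx$b <- 0
  expect_equal(predict(m3, vc$videos[1:4])$p_dep, p1$p_dep)

  # a single-class task is refused with the task named
  lab1 <- vc$labels
  lab1$y_dep <- 1L
  expect_error(train_risk_model(vc$videos, lab1, cfg, seed = 1), "depression")
  lab2 <- vc$labels
  lab2$y_anx <- 0L
  expect_error(train_risk_model(vc$videos, lab2, cfg, seed = 1), "anxiety")
})

test_that("spectral and frame input modes run through the same network", {
  vc <- generate_video_cohort(n = 8, frames = 32, image_size = c(16, 16),
                              seed = 61)
  for (mode in c("spectral", "frames")) {
    cfg <- risk_model_config(pool = 2, conv_channels = 2, d = 4, hidden = 3,
                             n_blocks = 1, epochs = 2, input_mode = mode)
    m <- train_risk_model(vc$videos, vc$labels, cfg, seed = 62)
    p <- predict(m, vc$videos[1:2])
    expect_true(all(is.finite(p$p_dep)))
  }
})
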