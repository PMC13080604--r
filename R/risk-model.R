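#' Risk-model configuration
#'
#' Architecture and optimization settings for the compact CNN-BiLSTM
#' dual-risk scorer. A video is cut into non-overlapping *time slices* of
#' `slice_len` frames; each slice is spatially average-pooled by `pool`,
#' passed through a `kernel` x `kernel` convolution over the slice's frames
#' (so the encoder sees within-slice motion), global mean+max pooled, and
#' projected through `n_blocks` residual fully-connected blocks to a
#' d-dimensional feature vector. The slice features are aggregated by a
#' bidirectional LSTM with hidden size `hidden`; the concatenated final
#' forward/backward states feed two sigmoid classification heads (depression
#' and anxiety risk probabilities) and two linear regression heads
#' (continuous severities). Training minimizes the weighted sum of the two
#' binary cross-entropies and the two squared-error terms
#' (`loss_weights`, default 1:1:0.5:0.5) with mini-batch Adam and decoupled
#' weight decay.
#'
#' @param slice_len frames per time slice
#' @param pool spatial average-pooling factor applied before the convolution
#' @param conv_channels number of convolution output channels
#' @param kernel spatial kernel size
#' @param n_blocks number of residual fully-connected blocks
#' @param d slice feature dimension
#' @param hidden LSTM hidden size m (the temporal state has length 2m)
#' @param input_mode what the encoder consumes per slice: `"spectral"`
#'   (default) feeds per-pixel within-slice FFT magnitude channels plus the
#'   within-slice mean residual and its magnitude -- a per-slice
#'   vibration-imaging map stack, free of within-slice phase; `"frames"`
#'   feeds the raw mean-removed frames. Both run through the identical
#'   network.
#' @param loss_weights named weights for `dep`, `anx`, `sev_dep`, `sev_anx`
#' @param lr Adam learning rate
#' @param weight_decay decoupled L2 penalty applied at each update (AdamW
#'   style); the main guard against memorizing nuisance structure (e.g.
#'   component phases) at desk-scale sample sizes
#' @param epochs training epochs
#' @param batch_size mini-batch size (seeded shuffling each epoch); set to
#'   `Inf` for full-batch training
#' @return a `risk_model_config` list
#' @export
risk_model_config <- function(slice_len = 8, pool = 4, conv_channels = 8,
                              kernel = 3, n_blocks = 2, d = 32, hidden = 32,
                              input_mode = c("spectral", "frames"),
                              loss_weights = c(dep = 1, anx = 1,
                                               sev_dep = 0.5, sev_anx = 0.5),
                              lr = 0.01, weight_decay = 0.01, epochs = 100,
                              batch_size = 32) {
  stop_if_not(slice_len >= 2 && pool >= 1 && kernel >= 1 && conv_channels >= 1,
              "invalid encoder geometry")
  stop_if_not(d >= 1 && hidden >= 1 && n_blocks >= 0, "invalid model sizes")
  stop_if_not(all(c("dep", "anx", "sev_dep", "sev_anx") %in% names(loss_weights)),
              "loss_weights needs dep/anx/sev_dep/sev_anx entries")
  input_mode <- match.arg(input_mode)
  structure(list(slice_len = as.integer(slice_len), pool = as.integer(pool),
                 input_mode = input_mode,
                 conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel), n_blocks = as.integer(n_blocks),
                 d = as.integer(d), hidden = as.integer(hidden),
                 loss_weights = loss_weights, lr = lr,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(min(batch_size, .Machine$integer.max))),
            class = "risk_model_config")
}

# ---- batch preparation (pool + im2col, done once per dataset) --------------

rm_geometry <- function(video_dim, config) {
  tt <- video_dim[1]; h <- video_dim[2]; w <- video_dim[3]
  ph <- h %/% config$pool; pw <- w %/% config$pool
  stop_if_not(ph >= config$kernel && pw >= config$kernel,
              "pooled slice (%d x %d) is smaller than the receptive-field minimum (%d)",
              ph, pw, config$kernel)
  s <- tt %/% config$slice_len
  stop_if_not(s >= 1, "clip shorter than one time slice (%d frames)", config$slice_len)
  n_ch <- if (identical(config$input_mode, "spectral"))
    config$slice_len %/% 2L + 2L else config$slice_len
  list(t = tt, h = h, w = w, ph = ph, pw = pw, s = s, n_channels = n_ch,
       npos = (ph - config$kernel + 1L) * (pw - config$kernel + 1L),
       in_dim = n_ch * config$kernel^2)
}

# linear indices into the pooled (T x Ph x Pw) array for the first slice's
# im2col matrix; later slices shift the time index by (s-1)*slice_len
# index into a (n_time x Ph x Pw) array whose first dimension holds the
# within-slice channels contiguously (raw frames, or spectral channels)
rm_im2col_index <- function(geom, config, n_time, n_ch) {
  k <- config$kernel
  pos <- expand.grid(r = seq_len(geom$ph - k + 1L), c = seq_len(geom$pw - k + 1L))
  off <- expand.grid(ch = seq_len(n_ch), dr = 0:(k - 1L), dc = 0:(k - 1L))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (q in seq_len(nrow(off))) {
    idx[, q] <- off$ch[q] + n_time * (pos$r + off$dr[q] - 1L) +
      n_time * geom$ph * (pos$c + off$dc[q] - 1L)
  }
  idx
}

rm_pool_spatial <- function(frames, pool, ph, pw) {
  if (pool == 1L) return(frames[, seq_len(ph), seq_len(pw), drop = FALSE])
  acc <- 0
  for (i in seq_len(pool)) for (j in seq_len(pool)) {
    acc <- acc + frames[, seq(i, ph * pool, by = pool), seq(j, pw * pool, by = pool),
                        drop = FALSE]
  }
  acc / pool^2
}

# stack all (video, slice) im2col blocks into one big matrix; rows are
# grouped contiguously by (video-major, then slice) so group g = (v-1)*S + s
rm_prepare <- function(videos, config) {
  stop_if_not(length(videos) > 0, "no videos")
  dims <- dim(videos[[1]])
  for (v in videos) stop_if_not(identical(dim(v), dims),
                                "all videos in a batch must share one geometry")
  geom <- rm_geometry(dims, config)
  spectral <- identical(config$input_mode, "spectral")
  n_time <- if (spectral) geom$s * geom$n_channels else geom$t
  idx <- rm_im2col_index(geom, config, n_time, geom$n_channels)
  ch_stride <- geom$n_channels
  b <- length(videos)
  x <- matrix(0, b * geom$s * geom$npos, geom$in_dim)
  row0 <- 0L
  for (v in seq_len(b)) {
    # the encoder consumes micro-motion residuals: per-pixel temporal mean
    # removed, so the static scene does not drown the movement signal
    frames <- unclass(videos[[v]])
    mu <- colMeans(matrix(frames, nrow = dims[1]))
    frames <- frames - rep(mu, each = dims[1])
    dim(frames) <- dims
    pooled <- rm_pool_spatial(frames, config$pool, geom$ph, geom$pw)
    pv <- if (spectral) rm_spectral_channels(pooled, geom, config)
          else as.numeric(pooled)
    stride <- if (spectral) ch_stride else config$slice_len
    for (s in seq_len(geom$s)) {
      x[row0 + seq_len(geom$npos), ] <- pv[idx + (s - 1L) * stride]
      row0 <- row0 + geom$npos
    }
  }
  list(x = x, b = b, s = geom$s, npos = geom$npos, geom = geom)
}

# per-slice, per-pixel spectral channels: the within-slice mean residual
# plus the FFT magnitudes at the slice's non-zero frequencies -- the same
# information a per-slice vibration-imaging map stack carries, and free of
# within-slice phase
rm_spectral_channels <- function(pooled, geom, config) {
  c_len <- config$slice_len; n_ch <- geom$n_channels
  p <- geom$ph * geom$pw
  out <- array(0, dim = c(n_ch * geom$s, geom$ph, geom$pw))
  pm <- matrix(pooled, nrow = geom$t, ncol = p)
  for (s in seq_len(geom$s)) {
    seg <- pm[((s - 1L) * c_len + 1L):(s * c_len), , drop = FALSE]
    mu <- colMeans(seg)
    sp <- Mod(stats::mvfft(seg - rep(mu, each = c_len)))[2:(c_len %/% 2L + 1L), ,
                                                         drop = FALSE]
    # mu: signed within-slice mean displacement; |mu|: its phase-free
    # magnitude, the sub-slice-frequency amplitude evidence
    block <- rbind(mu, abs(mu), sp)
    out[((s - 1L) * n_ch + 1L):(s * n_ch), , ] <- array(block,
                                                        c(n_ch, geom$ph, geom$pw))
  }
  as.numeric(out)
}

# row-subset of a prepared batch (selects whole videos)
rm_subset_prep <- function(prep, vids_idx) {
  rows_per_vid <- prep$s * prep$npos
  rows <- as.vector(outer(seq_len(rows_per_vid), (vids_idx - 1L) * rows_per_vid, `+`))
  list(x = prep$x[rows, , drop = FALSE], b = length(vids_idx), s = prep$s,
       npos = prep$npos, geom = prep$geom)
}

rm_subset_targets <- function(targets, idx) lapply(targets, `[`, idx)

# ---- parameters ------------------------------------------------------------

rm_init_params <- function(config, in_dim, seed = 1) {
  withr::local_seed(as.integer(seed))
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, 1 / sqrt(nr)), nr, nc)
  m <- config$hidden; d <- config$d; c1 <- config$conv_channels
  lstm_dir <- function() {
    b <- numeric(4 * m)
    b[(m + 1):(2 * m)] <- 1           # forget-gate bias init
    list(w = rmat(d, 4 * m), u = rmat(m, 4 * m), b = b)
  }
  blocks <- lapply(seq_len(config$n_blocks), function(i)
    list(a_w = rmat(d, d), a_b = numeric(d), b_w = rmat(d, d), b_b = numeric(d)))
  list(conv_w = rmat(in_dim, c1), conv_b = numeric(c1),
       proj_w = rmat(2 * c1, d), proj_b = numeric(d),
       blocks = blocks,
       lstm_fwd = lstm_dir(), lstm_bwd = lstm_dir(),
       head_dep = list(w = stats::rnorm(2 * m, 0, 0.1), b = 0),
       head_anx = list(w = stats::rnorm(2 * m, 0, 0.1), b = 0),
       head_sev_dep = list(w = stats::rnorm(2 * m, 0, 0.1), b = 0.5),
       head_sev_anx = list(w = stats::rnorm(2 * m, 0, 0.1), b = 0.5))
}

rm_flatten <- function(p) unlist(p, use.names = FALSE)

rm_unflatten <- function(vec, skeleton) {
  rel <- utils::relist(vec, skeleton)
  # relist drops matrix dims; restore them from the skeleton
  restore <- function(r, s) {
    if (is.list(s)) return(purrr::map2(r, s, restore))
    if (!is.null(dim(s))) dim(r) <- dim(s)
    r
  }
  restore(rel, skeleton)
}

# ---- forward ---------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# encoder: im2col rows -> slice feature matrix Z ((B*S) x d), with cache
rm_encode <- function(params, prep, config, keep = FALSE) {
  c1 <- config$conv_channels
  g <- prep$b * prep$s
  h1_pre <- sweep(prep$x %*% params$conv_w, 2, params$conv_b, `+`)
  h1 <- pmax(h1_pre, 0)
  grp <- rep(seq_len(g), each = prep$npos)
  m_mean <- rowsum(h1, grp, reorder = FALSE) / prep$npos
  m_max <- matrix(0, g, c1); imax <- matrix(0L, g, c1)
  for (c in seq_len(c1)) {
    mc <- matrix(h1[, c], prep$npos, g)
    ix <- max.col(t(mc), ties.method = "first")
    imax[, c] <- ix
    m_max[, c] <- mc[cbind(ix, seq_len(g))]
  }
  u <- cbind(m_mean, m_max)
  z_pre <- sweep(u %*% params$proj_w, 2, params$proj_b, `+`)
  z <- pmax(z_pre, 0)
  blk_cache <- vector("list", config$n_blocks)
  for (i in seq_along(params$blocks)) {
    bk <- params$blocks[[i]]
    r_pre <- sweep(z %*% bk$a_w, 2, bk$a_b, `+`)
    r_act <- pmax(r_pre, 0)
    z_out <- sweep(z + r_act %*% bk$b_w, 2, bk$b_b, `+`)
    if (keep) blk_cache[[i]] <- list(z_in = z, r_pre = r_pre, r_act = r_act)
    z <- z_out
  }
  out <- list(z = z)
  if (keep) out <- c(out, list(h1_pre = h1_pre, h1 = h1, imax = imax, u = u,
                               z_pre = z_pre, blk_cache = blk_cache, grp = grp))
  out
}

# one LSTM direction over a list of input matrices (processing order)
rm_lstm_forward <- function(z_steps, dir, m, keep = FALSE) {
  b <- nrow(z_steps[[1]])
  h <- matrix(0, b, m); cc <- matrix(0, b, m)
  cache <- if (keep) vector("list", length(z_steps)) else NULL
  for (t in seq_along(z_steps)) {
    g4 <- sweep(z_steps[[t]] %*% dir$w + h %*% dir$u, 2, dir$b, `+`)
    i_g <- sigmoid(g4[, 1:m, drop = FALSE])
    f_g <- sigmoid(g4[, (m + 1):(2 * m), drop = FALSE])
    g_g <- tanh(g4[, (2 * m + 1):(3 * m), drop = FALSE])
    o_g <- sigmoid(g4[, (3 * m + 1):(4 * m), drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- f_g * cc + i_g * g_g
    tc <- tanh(cc)
    h <- o_g * tc
    if (keep) cache[[t]] <- list(i = i_g, f = f_g, g = g_g, o = o_g,
                                 c_prev = c_prev, h_prev = h_prev, tc = tc)
  }
  list(h = h, cache = cache)
}

rm_lstm_backward <- function(dh_final, z_steps, dir, cache, m) {
  b <- nrow(dh_final)
  dw <- dir$w * 0; du <- dir$u * 0; db <- dir$b * 0
  dz_steps <- vector("list", length(z_steps))
  dh <- dh_final; dc <- matrix(0, b, m)
  for (t in rev(seq_along(z_steps))) {
    ch <- cache[[t]]
    do_g <- dh * ch$tc
    dc <- dc + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g; df <- dc * ch$c_prev; dg <- dc * ch$i
    dc_prev <- dc * ch$f
    dg4 <- cbind(di * ch$i * (1 - ch$i), df * ch$f * (1 - ch$f),
                 dg * (1 - ch$g^2), do_g * ch$o * (1 - ch$o))
    dw <- dw + crossprod(z_steps[[t]], dg4)
    du <- du + crossprod(ch$h_prev, dg4)
    db <- db + colSums(dg4)
    dz_steps[[t]] <- dg4 %*% t(dir$w)
    dh <- dg4 %*% t(dir$u)
    dc <- dc_prev
  }
  list(w = dw, u = du, b = db, dz_steps = dz_steps)
}

# full forward: prepared batch -> per-subject outputs (and caches)
rm_forward <- function(params, prep, config, keep = FALSE) {
  enc <- rm_encode(params, prep, config, keep = keep)
  m <- config$hidden
  step_rows <- function(t) (seq_len(prep$b) - 1L) * prep$s + t
  z_fwd <- lapply(seq_len(prep$s), function(t) enc$z[step_rows(t), , drop = FALSE])
  z_bwd <- rev(z_fwd)
  fwd <- rm_lstm_forward(z_fwd, params$lstm_fwd, m, keep = keep)
  bwd <- rm_lstm_forward(z_bwd, params$lstm_bwd, m, keep = keep)
  h <- cbind(fwd$h, bwd$h)
  head_lin <- function(hd) drop(h %*% hd$w) + hd$b
  out <- list(h = h,
              logit_dep = head_lin(params$head_dep),
              logit_anx = head_lin(params$head_anx),
              sev_dep = head_lin(params$head_sev_dep),
              sev_anx = head_lin(params$head_sev_anx))
  out$p_dep <- sigmoid(out$logit_dep)
  out$p_anx <- sigmoid(out$logit_anx)
  if (keep) out <- c(out, list(enc = enc, z_fwd = z_fwd, z_bwd = z_bwd,
                               fwd = fwd, bwd = bwd, step_rows = step_rows))
  out
}

# loss + full gradient; targets: y_dep/y_anx in {0,1}, t_sdep/t_sanx in [0,1]
rm_loss_grad <- function(params, prep, targets, config) {
  fw <- rm_forward(params, prep, config, keep = TRUE)
  b <- prep$b
  lw <- config$loss_weights
  p_dep <- clip_prob(fw$p_dep); p_anx <- clip_prob(fw$p_anx)
  bce <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))
  loss <- lw[["dep"]] * bce(p_dep, targets$y_dep) +
    lw[["anx"]] * bce(p_anx, targets$y_anx) +
    lw[["sev_dep"]] * mean((fw$sev_dep - targets$t_sdep)^2) +
    lw[["sev_anx"]] * mean((fw$sev_anx - targets$t_sanx)^2)

  dl_dep <- lw[["dep"]] * (fw$p_dep - targets$y_dep) / b
  dl_anx <- lw[["anx"]] * (fw$p_anx - targets$y_anx) / b
  ds_dep <- lw[["sev_dep"]] * 2 * (fw$sev_dep - targets$t_sdep) / b
  ds_anx <- lw[["sev_anx"]] * 2 * (fw$sev_anx - targets$t_sanx) / b

  g <- params  # grads share the parameter skeleton
  head_grad <- function(dl) list(w = drop(crossprod(fw$h, dl)), b = sum(dl))
  g$head_dep <- head_grad(dl_dep); g$head_anx <- head_grad(dl_anx)
  g$head_sev_dep <- head_grad(ds_dep); g$head_sev_anx <- head_grad(ds_anx)

  dh <- outer(dl_dep, params$head_dep$w) + outer(dl_anx, params$head_anx$w) +
    outer(ds_dep, params$head_sev_dep$w) + outer(ds_anx, params$head_sev_anx$w)
  m <- config$hidden
  gb_f <- rm_lstm_backward(dh[, 1:m, drop = FALSE], fw$z_fwd, params$lstm_fwd,
                           fw$fwd$cache, m)
  gb_b <- rm_lstm_backward(dh[, (m + 1):(2 * m), drop = FALSE], fw$z_bwd,
                           params$lstm_bwd, fw$bwd$cache, m)
  g$lstm_fwd <- gb_f[c("w", "u", "b")]
  g$lstm_bwd <- gb_b[c("w", "u", "b")]

  dz <- matrix(0, prep$b * prep$s, config$d)
  for (t in seq_len(prep$s)) {
    rows <- fw$step_rows(t)
    dz[rows, ] <- dz[rows, ] + gb_f$dz_steps[[t]] + gb_b$dz_steps[[prep$s + 1L - t]]
  }

  enc <- fw$enc
  for (i in rev(seq_along(params$blocks))) {
    bk <- params$blocks[[i]]; ch <- enc$blk_cache[[i]]
    g$blocks[[i]]$b_w <- crossprod(ch$r_act, dz)
    g$blocks[[i]]$b_b <- colSums(dz)
    dr <- (dz %*% t(bk$b_w)) * (ch$r_pre > 0)
    g$blocks[[i]]$a_w <- crossprod(ch$z_in, dr)
    g$blocks[[i]]$a_b <- colSums(dr)
    dz <- dz + dr %*% t(bk$a_w)
  }
  dz_pre <- dz * (enc$z_pre > 0)
  g$proj_w <- crossprod(enc$u, dz_pre)
  g$proj_b <- colSums(dz_pre)
  du <- dz_pre %*% t(params$proj_w)
  c1 <- config$conv_channels
  d_mean <- du[, 1:c1, drop = FALSE]
  d_max <- du[, (c1 + 1):(2 * c1), drop = FALSE]
  dh1 <- d_mean[enc$grp, , drop = FALSE] / prep$npos
  gtot <- prep$b * prep$s
  for (c in seq_len(c1)) {
    rows <- (seq_len(gtot) - 1L) * prep$npos + enc$imax[, c]
    dh1[cbind(rows, c)] <- dh1[cbind(rows, c)] + d_max[, c]
  }
  dh1 <- dh1 * (enc$h1_pre > 0)
  g$conv_w <- crossprod(prep$x, dh1)
  g$conv_b <- colSums(dh1)
  list(loss = loss, grads = g)
}

# ---- training --------------------------------------------------------------

#' Train the CNN-BiLSTM dual-risk scorer
#'
#' Full-batch Adam on the weighted multi-task loss (two binary
#' cross-entropies for the depression and anxiety risk heads plus two
#' squared-error terms for the severity regression heads; 1-5 severities are
#' rescaled to [0, 1] as regression targets). Fully deterministic under
#' `seed`: identical data, config and seed give identical weights.
#'
#' @param videos list of [video_cube()]s sharing one geometry
#' @param labels data frame aligned with `videos`, with columns `y_dep`,
#'   `y_anx` (binary) and `sev_dep`, `sev_anx` (1-5)
#' @param config a [risk_model_config()]
#' @param seed integer seed for weight initialization
#' @return a `risk_model` object (weights, config, loss history)
#' @export
train_risk_model <- function(videos, labels, config = risk_model_config(),
                             seed = 1) {
  stop_if_not(length(videos) == nrow(labels), "videos/labels lengths differ")
  for (task in c("y_dep", "y_anx")) {
    cls <- unique(labels[[task]])
    if (length(cls) < 2)
      stop(sprintf("task %s has a single class in the training labels",
                   if (task == "y_dep") "depression" else "anxiety"), call. = FALSE)
  }
  stop_if_not(all(labels$sev_dep %in% 1:5) && all(labels$sev_anx %in% 1:5),
              "severity labels must be integers in 1..5")
  prep <- rm_prepare(videos, config)
  targets <- list(y_dep = as.numeric(labels$y_dep),
                  y_anx = as.numeric(labels$y_anx),
                  t_sdep = (labels$sev_dep - 1) / 4,
                  t_sanx = (labels$sev_anx - 1) / 4)
  withr::local_seed(as.integer(seed))
  params <- rm_init_params(config, prep$geom$in_dim, seed = seed)
  flat <- rm_flatten(params)
  m_adam <- numeric(length(flat)); v_adam <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- prep$b
  bs <- min(config$batch_size %||% n, n)
  history <- numeric(config$epochs)
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- if (bs < n) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = bs)) {
      take <- ord[start:min(start + bs - 1L, n)]
      lg <- rm_loss_grad(params, rm_subset_prep(prep, take),
                         rm_subset_targets(targets, take), config)
      ep_loss <- ep_loss + lg$loss * length(take)
      gflat <- rm_flatten(lg$grads)
      step <- step + 1L
      m_adam <- b1 * m_adam + (1 - b1) * gflat
      v_adam <- b2 * v_adam + (1 - b2) * gflat^2
      mh <- m_adam / (1 - b1^step); vh <- v_adam / (1 - b2^step)
      flat <- flat - config$lr * (mh / (sqrt(vh) + eps) +
                                    (config$weight_decay %||% 0) * flat)
      params <- rm_unflatten(flat, params)
    }
    history[ep] <- ep_loss / n
  }
  structure(list(params = params, config = config, loss_history = history,
                 n_train = length(videos), seed = seed),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> d=%d hidden=%d blocks=%d | trained %d epochs on %d clips (loss %.4f -> %.4f)\n",
              x$config$d, x$config$hidden, x$config$n_blocks,
              length(x$loss_history), x$n_train,
              x$loss_history[1], x$loss_history[length(x$loss_history)]))
  invisible(x)
}

#' Predict risk scores for videos
#'
#' A pure function of (video, weights): repeated calls agree exactly.
#' Severity head outputs are mapped back to the 1-5 scale.
#'
#' @param object a trained `risk_model`
#' @param videos a [video_cube()] or list of cubes
#' @param ... unused
#' @return tibble with `p_dep`, `p_anx`, `sev_dep`, `sev_anx` per video
#' @export
predict.risk_model <- function(object, videos, ...) {
  if (inherits(videos, "video_cube")) videos <- list(videos)
  prep <- rm_prepare(videos, object$config)
  fw <- rm_forward(object$params, prep, object$config)
  stop_if_not(all(is.finite(fw$h)), "non-finite temporal state")
  tibble::tibble(p_dep = fw$p_dep, p_anx = fw$p_anx,
                 sev_dep = 1 + 4 * fw$sev_dep, sev_anx = 1 + 4 * fw$sev_anx)
}

#' Encode a video into its slice feature sequence
#'
#' Runs the convolutional encoder only, returning one d-dimensional feature
#' vector per time slice.
#'
#' @param video a [video_cube()]
#' @param model a trained `risk_model` (or a list with `params` and `config`)
#' @return an S x d matrix, S = number of slices
#' @export
encode_frames <- function(video, model) {
  prep <- rm_prepare(list(video), model$config)
  rm_encode(model$params, prep, model$config)$z
}

#' Aggregate a feature sequence with the bidirectional LSTM
#'
#' Returns the temporal state h: the concatenation of the final forward and
#' final backward hidden states (length 2m).
#'
#' @param features T x d matrix of slice features (T >= 1)
#' @param lstm either a trained `risk_model` or a list with `lstm_fwd` /
#'   `lstm_bwd`, each holding `w` (d x 4m), `u` (m x 4m), `b` (4m)
#' @return numeric vector of length 2m
#' @export
aggregate_sequence <- function(features, lstm) {
  stop_if_not(is.matrix(features) && nrow(features) >= 1, "empty feature sequence")
  pars <- if (inherits(lstm, "risk_model")) lstm$params else lstm
  m <- nrow(pars$lstm_fwd$u)
  stop_if_not(ncol(features) == nrow(pars$lstm_fwd$w),
              "feature dimension (%d) does not match LSTM input dimension (%d)",
              ncol(features), nrow(pars$lstm_fwd$w))
  z_steps <- lapply(seq_len(nrow(features)), function(t) features[t, , drop = FALSE])
  fwd <- rm_lstm_forward(z_steps, pars$lstm_fwd, m)
  bwd <- rm_lstm_forward(rev(z_steps), pars$lstm_bwd, m)
  c(drop(fwd$h), drop(bwd$h))
}

#' Risk scores from a temporal state
#'
#' The multi-task heads: `p = sigmoid(w . h + b)` for each classification
#' head and a linear map for each severity head.
#'
#' @param h temporal state vector (length 2m), finite
#' @param heads list with `head_dep`, `head_anx`, `head_sev_dep`,
#'   `head_sev_anx`, each a list `w`, `b` (a trained `risk_model` also works)
#' @return tibble `p_dep`, `p_anx`, `sev_dep`, `sev_anx`
#' @export
predict_risk <- function(h, heads) {
  stop_if_not(is.numeric(h) && all(is.finite(h)), "temporal state must be finite")
  if (inherits(heads, "risk_model")) heads <- heads$params
  lin <- function(hd) {
    stop_if_not(length(hd$w) == length(h), "head weight length does not match h")
    sum(hd$w * h) + hd$b
  }
  tibble::tibble(p_dep = sigmoid(lin(heads$head_dep)),
                 p_anx = sigmoid(lin(heads$head_anx)),
                 sev_dep = 1 + 4 * lin(heads$head_sev_dep),
                 sev_anx = 1 + 4 * lin(heads$head_sev_anx))
}
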