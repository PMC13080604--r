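# Independent brute-force oracles used across the suite. These deliberately
# use plain loops / direct formulas, not the package's vectorized paths.

naive_amplitude_map <- function(video, window) {
  d <- dim(video)
  tt <- d[1]
  n_win <- tt %/% window
  out <- matrix(0, d[2], d[3])
  for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    acc <- 0
    for (w in seq_len(n_win)) {
      idx <- ((w - 1) * window + 1):(w * window)
      u <- video[idx, r, cc]
      acc <- acc + mean(abs(u - mean(u)))
    }
    out[r, cc] <- acc / n_win
  }
  out
}

# per-pixel STFT dominant frequency, written as a direct per-pixel loop
naive_frequency_map <- function(video, band, len, overlap) {
  d <- dim(video); fs <- attr(video, "frame_rate"); tt <- d[1]
  hop <- max(1, round(len * (1 - overlap)))
  starts <- seq(1, tt - len + 1, by = hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / (len - 1))
  freqs <- (seq_len(len %/% 2)) * fs / len
  keep <- which(freqs >= band[1] & freqs <= band[2])
  out <- matrix(NA_real_, d[2], d[3])
  for (r in seq_len(d[2])) for (cc in seq_len(d[3])) {
    s <- video[, r, cc]
    mag <- rep(0, length(keep))
    for (s0 in starts) {
      seg <- s[s0:(s0 + len - 1)]
      sp <- abs(fft((seg - mean(seg)) * win))[1 + seq_len(len %/% 2)]
      mag <- mag + sp[keep]
    }
    if (sum(mag) > 0) out[r, cc] <- freqs[keep][which(mag == max(mag))[1]]
  }
  out
}

naive_hist_entropy_bits <- function(vals, n_bins) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(0)
  counts <- numeric(n_bins)
  for (v in vals) {
    b <- min(n_bins, 1 + floor((v - rng[1]) / diff(rng) * n_bins))
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

brute_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  y <- as.logical(labels)
  best_j <- -Inf; best_ct <- NA
  for (ct in cand) {
    pos <- scores >= ct
    j <- sum(pos & y) / sum(y) + sum(!pos & !y) / sum(!y) - 1
    if (j > best_j + 1e-12) { best_j <- j; best_ct <- ct }
  }
  list(threshold = best_ct, j = best_j)
}

pairwise_auc <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]; sn <- scores[!y]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

brute_macro_f1 <- function(cm) {
  k <- nrow(cm)
  f1s <- numeric(k)
  for (i in seq_len(k)) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    f1s[i] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  mean(f1s)
}

# one hand-unrolled LSTM cell step from a zero initial state
lstm_step_oracle <- function(z, w, u, b, m) {
  g <- as.numeric(z %*% w) + b           # h_0 = 0
  sig <- function(x) 1 / (1 + exp(-x))
  i <- sig(g[1:m]); f <- sig(g[(m + 1):(2 * m)])
  gg <- tanh(g[(2 * m + 1):(3 * m)]); o <- sig(g[(3 * m + 1):(4 * m)])
  cc <- i * gg
  o * tanh(cc)
}

make_tone_video <- function(freq, fps = 32, secs = 10, hw = c(8, 8),
                            amplitude_um = 300, noise_sd = 0.1, seed = 1,
                            mask = NULL) {
  sp <- vibration_spec(frame_rate = fps, duration = secs, image_size = hw,
                       components = list(list(frequency_hz = freq,
                                              amplitude_um = amplitude_um,
                                              mask = mask)),
                       noise_sd = noise_sd)
  generate_video(sp, seed = seed)
}

tiny_model_config <- function(...) {
  risk_model_config(slice_len = 4, pool = 2, conv_channels = 2, kernel = 2,
                    n_blocks = 1, d = 4, hidden = 3, epochs = 3, ...)
}
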