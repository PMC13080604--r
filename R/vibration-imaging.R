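#' Per-pixel amplitude map (mean absolute deviation)
#'
#' The classic vibration-imaging amplitude map: for each pixel, the mean
#' absolute deviation of its intensity about its within-window mean,
#' \deqn{A(x,y) = \frac{1}{N}\sum_{i=1}^{N} |U_{x,y,i} - \bar U_{x,y}|,}
#' computed over consecutive non-overlapping windows of `window` frames and
#' averaged across windows when the clip is longer than one window. Trailing
#' frames that do not fill a window are dropped.
#'
#' @param video a [video_cube()]
#' @param window window length N in frames; default the whole clip
#' @return an `amplitude_map`: H x W numeric matrix (all entries >= 0, zero
#'   exactly where the pixel is constant within every window), with
#'   attributes `window` and `n_windows`
#' @export
compute_amplitude_map <- function(video, window = NULL) {
  stop_if_not(inherits(video, "video_cube"), "`video` must be a video_cube")
  tt <- n_frames(video)
  window <- as.integer(window %||% tt)
  stop_if_not(window >= 2, "`window` must be at least 2 frames")
  stop_if_not(window <= tt, "`window` (%d) exceeds the clip length (%d frames)",
              window, tt)
  m <- cube_matrix(video)
  n_win <- tt %/% window
  acc <- 0
  for (w in seq_len(n_win)) {
    seg <- m[((w - 1) * window + 1):(w * window), , drop = FALSE]
    mu <- colMeans(seg)
    acc <- acc + colMeans(abs(seg - rep(mu, each = window)))
  }
  d <- dim(video)
  structure(matrix(acc / n_win, d[2], d[3]),
            window = window, n_windows = n_win,
            class = c("amplitude_map", "matrix", "array"))
}

#' Per-pixel dominant-frequency map via the short-time Fourier transform
#'
#' For each pixel's intensity time series \eqn{s_{x,y}(t)}, magnitudes of a
#' Hann-windowed STFT are averaged across segments, and
#' \eqn{F(x,y) = \arg\max_{f \in B} |STFT\{s_{x,y}\}(f)|} is taken over the
#' discrete frequencies inside the band `B` (default the psychologically
#' relevant 0.1-10 Hz). The DC bin is never a candidate. Ties break toward
#' the lowest frequency. Pixels with zero in-band power (e.g. a constant
#' series) get `NA`, the undefined sentinel.
#'
#' @param video a [video_cube()]
#' @param band `c(f_lo, f_hi)` in Hz, strictly inside `(0, frame_rate/2)`
#' @param stft_window segment length in frames; default `min(T, 4 s)` so the
#'   frequency resolution reaches 0.25 Hz or better at typical frame rates
#' @param stft_overlap fractional overlap of consecutive segments in `[0, 1)`
#' @return a `frequency_map`: H x W matrix of dominant frequencies in Hz
#'   (`NA` = undefined), with attributes `band`, `stft_window`, `frequencies`
#' @export
compute_frequency_map <- function(video, band = c(0.1, 10), stft_window = NULL,
                                  stft_overlap = 0.5) {
  stop_if_not(inherits(video, "video_cube"), "`video` must be a video_cube")
  fs <- frame_rate(video); tt <- n_frames(video)
  stop_if_not(length(band) == 2 && band[1] < band[2], "`band` must be c(f_lo, f_hi)")
  stop_if_not(band[1] > 0 && band[2] < fs / 2,
              "`band` must lie strictly inside (0, Nyquist = %.3g Hz)", fs / 2)
  stop_if_not(stft_overlap >= 0 && stft_overlap < 1, "`stft_overlap` must be in [0, 1)")
  len <- as.integer(stft_window %||% min(tt, round(4 * fs)))
  stop_if_not(len >= 4 && len <= tt, "`stft_window` must be in [4, T]")

  freqs <- (seq_len(len %/% 2)) * fs / len      # DC (k = 0) excluded outright
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(in_band))
    stop(sprintf("band (%.3g, %.3g) Hz contains no STFT bin at window %d / %g fps",
                 band[1], band[2], len, fs), call. = FALSE)

  hop <- max(1L, as.integer(round(len * (1 - stft_overlap))))
  starts <- seq(1L, tt - len + 1L, by = hop)
  win <- hann_window(len)
  m <- cube_matrix(video)
  mag <- 0
  for (s0 in starts) {
    seg <- m[s0:(s0 + len - 1L), , drop = FALSE]
    seg <- (seg - rep(colMeans(seg), each = len)) * win   # de-mean: no DC leakage
    sp <- stats::mvfft(seg)
    mag <- mag + Mod(sp[1L + seq_len(len %/% 2), , drop = FALSE])
  }
  mag <- mag[in_band, , drop = FALSE] / length(starts)

  best <- apply_argmax_lowest(mag)
  fvals <- freqs[in_band][best]
  fvals[colSums(mag) <= 0 | is.na(best)] <- NA_real_
  d <- dim(video)
  structure(matrix(fvals, d[2], d[3]),
            band = band, stft_window = len, stft_overlap = stft_overlap,
            frequencies = freqs[in_band],
            class = c("frequency_map", "matrix", "array"))
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# column-wise argmax with ties broken toward the first (lowest-frequency) row
apply_argmax_lowest <- function(m) {
  idx <- integer(ncol(m))
  for (j in seq_len(ncol(m))) idx[j] <- which(m[, j] == max(m[, j]))[1]
  idx
}

#' Regional summary statistics of a feature map
#'
#' Mean, variance and histogram entropy of an amplitude or frequency map
#' over a pixel region, the classic hand-crafted regional features. The
#' entropy is the Shannon entropy (bits) of an `n_bins` equal-width
#' histogram of the masked, defined values; a constant region has entropy 0.
#' Variance is the population variance (mean squared deviation over the
#' region's pixels).
#'
#' @param map an `amplitude_map`, `frequency_map`, or plain matrix
#' @param region logical matrix of the same size; default all pixels
#' @param n_bins number of equal-width histogram bins (default 16)
#' @return tibble with `mean`, `variance`, `entropy_bits`, `n_pixels`
#' @export
region_statistics <- function(map, region = NULL, n_bins = 16) {
  stop_if_not(is.matrix(map), "`map` must be a matrix")
  region <- region %||% matrix(TRUE, nrow(map), ncol(map))
  stop_if_not(all(dim(region) == dim(map)), "`region` must match the map size")
  stop_if_not(any(region), "`region` is empty")
  vals <- map[region]
  vals <- vals[is.finite(vals)]
  if (!length(vals))
    stop("all pixels in the region are undefined", call. = FALSE)
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    ent <- 0
  } else {
    counts <- tabulate(pmin(n_bins, 1L + floor((vals - rng[1]) / diff(rng) * n_bins)),
                       nbins = n_bins)
    ent <- shannon_entropy_bits(counts)
  }
  tibble::tibble(mean = mean(vals),
                 variance = mean((vals - mean(vals))^2),
                 entropy_bits = ent,
                 n_pixels = length(vals))
}

#' Spectral features of a pixel (or region-averaged) time series
#'
#' The two spectral features that separate cases from controls in
#' micro-vibration studies: the fraction of in-band power below a low-
#' frequency cut, and the normalized spectral entropy of the in-band power
#' distribution (0 = a single tone, 1 = a flat spectrum) as a declared proxy
#' for signal complexity. Power is the periodogram of the mean-removed
#' series; the in-band bins are those with frequency in `band`.
#'
#' @param series numeric vector, the intensity time series
#' @param frame_rate sampling rate in Hz
#' @param band `c(f_lo, f_hi)` in Hz
#' @param low_cut frequency (Hz) splitting "low" from "high" in-band power;
#'   bins strictly below `low_cut` count as low. Must lie inside `band`.
#' @return tibble with `low_freq_energy_ratio` and `spectral_entropy`
#' @export
spectral_features <- function(series, frame_rate, band = c(0.1, 10), low_cut = 1) {
  stop_if_not(is.numeric(series) && length(series) >= 4, "`series` too short")
  stop_if_not(low_cut > band[1] && low_cut < band[2], "`low_cut` must be inside `band`")
  n <- length(series)
  freqs <- (seq_len(n %/% 2)) * frame_rate / n
  pw <- Mod(stats::fft(series - mean(series)))[1L + seq_len(n %/% 2)]^2 / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  stop_if_not(any(in_band), "band contains no frequency bin for this series length")
  p <- pw[in_band]; f <- freqs[in_band]
  tot <- sum(p)
  if (tot <= 0) stop("zero in-band power: spectral features undefined", call. = FALSE)
  ratio <- sum(p[f < low_cut]) / tot
  k <- length(p)
  sent <- if (k > 1) shannon_entropy_bits(p) / log2(k) else 0
  tibble::tibble(low_freq_energy_ratio = ratio, spectral_entropy = sent)
}

#' Region-mean intensity series of a video cube
#'
#' Averages the pixel time series over a region, a convenient single series
#' for [spectral_features()].
#' @param video a [video_cube()]
#' @param region logical H x W mask; default all pixels
#' @return numeric vector of length T
#' @export
region_series <- function(video, region = NULL) {
  d <- dim(video)
  region <- region %||% matrix(TRUE, d[2], d[3])
  m <- cube_matrix(video)
  rowMeans(m[, which(region), drop = FALSE])
}
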