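#' Specification of a synthetic micro-vibration video
#'
#' Describes the sinusoidal micro-movement components injected into a
#' synthetic head-region video. Head-neck micro-vibrations of interest live
#' in the 0.1-10 Hz band with amplitudes of roughly 10-1000 micrometres;
#' `micron_to_intensity` is the declared linear scale mapping micrometre
#' amplitudes onto pixel-intensity units (no camera model is simulated).
#'
#' @param frame_rate acquisition rate in frames per second; default 32 fps so
#'   the Nyquist limit (16 Hz) clears the 10 Hz band ceiling
#' @param duration clip length in seconds
#' @param image_size `c(H, W)` in pixels
#' @param components list of components, each a list with `frequency_hz`,
#'   `amplitude_um` and optionally `mask` (logical H x W matrix; default the
#'   central 50% rectangle). Frequencies must lie below Nyquist.
#' @param noise_sd additive Gaussian pixel noise, intensity units
#' @param base baseline intensity of every pixel
#' @param micron_to_intensity scale factor from micrometres to intensity units
#' @return a `vibration_spec` list
#' @export
vibration_spec <- function(frame_rate = 32, duration = 4,
                           image_size = c(32, 32), components = list(),
                           noise_sd = 0.5, base = 100,
                           micron_to_intensity = 0.01) {
  stop_if_not(frame_rate > 0 && duration > 0, "frame_rate and duration must be positive")
  stop_if_not(length(image_size) == 2 && all(image_size >= 1),
              "`image_size` must be c(H, W)")
  nyq <- frame_rate / 2
  for (cp in components) {
    f <- cp$frequency_hz
    stop_if_not(is.numeric(f) && f > 0,
                "component frequencies must be positive")
    stop_if_not(f < nyq,
                "component frequency %.3g Hz is at or above Nyquist (%.3g Hz)", f, nyq)
    stop_if_not(cp$amplitude_um >= 0, "component amplitudes must be >= 0")
  }
  stop_if_not(noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(list(frame_rate = frame_rate, duration = duration,
                 image_size = as.integer(image_size), components = components,
                 noise_sd = noise_sd, base = base,
                 micron_to_intensity = micron_to_intensity),
            class = "vibration_spec")
}

#' Generate a synthetic micro-vibration video
#'
#' Each component contributes `amplitude * sin(2*pi*f*t + phase)` (a single
#' random phase per component, shared across its region, i.e. the region
#' moves coherently) to every pixel in its mask, on top of a constant
#' baseline and i.i.d. Gaussian noise. The injected components are recorded
#' as ground truth on the returned cube.
#'
#' @param spec a [vibration_spec()]
#' @param seed integer; fixes phases and noise, so identical `spec` + `seed`
#'   give bit-identical cubes
#' @return a [video_cube()] with a `ground_truth` attribute
#' @export
generate_video <- function(spec, seed = 1) {
  stop_if_not(inherits(spec, "vibration_spec"), "`spec` must be a vibration_spec")
  withr::local_seed(as.integer(seed))
  tt <- round(spec$duration * spec$frame_rate)
  h <- spec$image_size[1]; w <- spec$image_size[2]
  t_sec <- (seq_len(tt) - 1) / spec$frame_rate
  cube <- array(spec$base, dim = c(tt, h, w))
  gt <- list()
  for (k in seq_along(spec$components)) {
    cp <- spec$components[[k]]
    mask <- cp$mask %||% central_mask(h, w)
    stop_if_not(is.logical(mask) && all(dim(mask) == c(h, w)),
                "component mask must be a logical H x W matrix")
    phase <- stats::runif(1, 0, 2 * pi)
    amp <- cp$amplitude_um * spec$micron_to_intensity
    sig <- amp * sin(2 * pi * cp$frequency_hz * t_sec + phase)
    idx <- which(mask)                       # pixel columns in T x P view
    if (length(idx)) {
      flat <- matrix(cube, nrow = tt)
      flat[, idx] <- flat[, idx] + sig
      cube <- array(flat, dim = c(tt, h, w))
    }
    gt[[k]] <- tibble::tibble(component = k, frequency_hz = cp$frequency_hz,
                              amplitude_um = cp$amplitude_um,
                              amplitude_intensity = amp,
                              phase = phase, n_pixels = length(idx))
  }
  if (spec$noise_sd > 0)
    cube <- cube + array(stats::rnorm(length(cube), 0, spec$noise_sd), dim = dim(cube))
  video_cube(cube, spec$frame_rate,
             ground_truth = if (length(gt)) dplyr::bind_rows(gt) else
               tibble::tibble(component = integer(), frequency_hz = numeric(),
                              amplitude_um = numeric(), amplitude_intensity = numeric(),
                              phase = numeric(), n_pixels = integer()))
}

#' Generate a labelled cohort of synthetic micro-vibration videos
#'
#' Emulates the class-dependent spectral signature the screening model is
#' meant to learn: cases carry increased low-frequency energy. Every subject
#' gets an 8 Hz "common" head-movement component; the amplitude of a 0.5 Hz
#' component grows with depression severity and that of a 4 Hz component
#' with anxiety severity (the depression signature sits at the slow end of
#' the 0.1-10 Hz band, the anxiety signature in the tremor-like mid band).
#' At `effect_scale = 1` the amplitude coupling is 40 um per severity level
#' with a 20 um residual spread, giving a standardized class separation of
#' a little over 2 SD at the severity >= 3 cutoff. `effect_scale = 0` severs
#' the link between class and signal (a null cohort: amplitudes are drawn
#' from one common distribution).
#'
#' @param n number of subjects
#' @param prev_dep,prev_anx class prevalences used for the fixed-count split
#'   (defaults mirror a 98-subject cohort with 73 and 52 positives)
#' @param effect_scale multiplier on the severity-amplitude coupling
#' @param frames,image_size,frame_rate video geometry (kept small by default:
#'   64 frames of 32 x 32 px at 32 fps, i.e. 2 s clips)
#' @param noise_sd pixel noise, intensity units
#' @param seed integer seed fixing everything
#' @return list with `videos` (list of [video_cube()]) and `labels` (tibble:
#'   subject_id, sev_dep, sev_anx, y_dep, y_anx)
#' @export
generate_video_cohort <- function(n = 200, prev_dep = 73 / 98, prev_anx = 52 / 98,
                                  effect_scale = 1, frames = 64,
                                  image_size = c(32, 32), frame_rate = 32,
                                  noise_sd = 1, seed = 1) {
  withr::local_seed(as.integer(seed))
  n_dep <- round(n * prev_dep); n_anx <- round(n * prev_anx)
  lab <- cohort_severities(n, n_dep, n_anx)
  # severity -> component amplitude (micrometres); within-class spread
  # ~33 um vs an 80 um between-class mean gap => ~2.4 SD separation at scale 1
  amp_from_sev <- function(sev) {
    if (effect_scale > 0) 100 + 40 * effect_scale * sev + stats::rnorm(n, 0, 20)
    else stats::rnorm(n, 200, 40)
  }
  amp_dep <- pmax(10, amp_from_sev(lab$sev_dep))
  amp_anx <- pmax(10, amp_from_sev(lab$sev_anx))
  h <- image_size[1]; w <- image_size[2]
  mask <- central_mask(h, w, 0.75)
  vids <- vector("list", n)
  seeds <- sample.int(.Machine$integer.max, n)
  for (i in seq_len(n)) {
    sp <- vibration_spec(
      frame_rate = frame_rate, duration = frames / frame_rate,
      image_size = image_size, noise_sd = noise_sd,
      components = list(
        list(frequency_hz = 0.5, amplitude_um = amp_dep[i], mask = mask),
        list(frequency_hz = 4, amplitude_um = amp_anx[i], mask = mask),
        list(frequency_hz = 8, amplitude_um = 120, mask = mask)))
    vids[[i]] <- generate_video(sp, seed = seeds[i])
  }
  list(videos = vids,
       labels = tibble::tibble(subject_id = seq_len(n),
                               sev_dep = lab$sev_dep, sev_anx = lab$sev_anx,
                               y_dep = as.integer(lab$sev_dep >= 3),
                               y_anx = as.integer(lab$sev_anx >= 3)))
}

# fixed-count severity assignment shared by the video and tabular generators:
# exactly n_dep / n_anx subjects get severity >= 3 on each axis
cohort_severities <- function(n, n_dep, n_anx) {
  stop_if_not(n_dep <= n && n_anx <= n && n_dep >= 0 && n_anx >= 0,
              "positive counts cannot exceed the cohort size")
  sev_axis <- function(n_pos) {
    sev <- integer(n)
    pos <- sample.int(n, n_pos)
    neg <- setdiff(seq_len(n), pos)
    sev[pos] <- sample(3:5, n_pos, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    sev[neg] <- sample(1:2, length(neg), replace = TRUE)
    sev
  }
  list(sev_dep = sev_axis(n_dep), sev_anx = sev_axis(n_anx))
}
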