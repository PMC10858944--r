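# Synthetic ground truth: orientation-column cortex phantoms with
# stimulus-entrained GCaMP dynamics and physiological noise, and a
# USAF-1951 resolution target.

#' Synthetic orientation-preference map with pinwheels
#'
#' Complex Gaussian white noise is filtered by an annular spectral band
#' centred at the column periodicity; the preferred orientation is half the
#' argument of the filtered field, which reproduces the semi-periodic
#' organization of primate V1 orientation columns including pinwheel
#' singularities.
#'
#' @param shape map size in pixels (scalar or length 2).
#' @param pixel_pitch_obj object-plane pixel pitch in micrometres.
#' @param periodicity column periodicity in cycles/mm (primate V1: ~1.2).
#' @param bandwidth relative width (SD / centre) of the Gaussian annulus.
#' @param seed integer seed.
#' @return list with `pref_map` (degrees in `[0, 180)`), `strength`
#'   (normalized magnitude of the filtered field, in `[0, 1]`),
#'   `pixel_pitch_obj`, `periodicity`.
#' @export
generate_orientation_map <- function(shape, pixel_pitch_obj = 20,
                                     periodicity = 1.2, bandwidth = 0.25,
                                     seed = 1L) {
  if (length(shape) == 1) shape <- c(shape, shape)
  nyq <- 1 / (2 * pixel_pitch_obj * 1e-3)   # cycles/mm
  if (periodicity >= nyq)
    stop("periodicity not resolvable at this pixel pitch", call. = FALSE)
  z <- with_seed(seed, {
    matrix(stats::rnorm(prod(shape)), shape[1], shape[2]) +
      1i * matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  })
  fy <- fft_freq(shape[1], pixel_pitch_obj * 1e-3)  # cycles/mm
  fx <- fft_freq(shape[2], pixel_pitch_obj * 1e-3)
  r <- sqrt(outer(fy^2, fx^2, "+"))
  band <- exp(-(r - periodicity)^2 / (2 * (bandwidth * periodicity)^2))
  band[r == 0] <- 0
  zf <- ifft2(fft2(z) * band)
  theta <- (Arg(zf) %% (2 * pi)) / 2 * (180 / pi)   # [0, 180)
  strength <- Mod(zf) / max(Mod(zf))
  list(pref_map = theta, strength = strength,
       pixel_pitch_obj = pixel_pitch_obj, periodicity = periodicity)
}

#' Cortex phantom
#'
#' Ground-truth scene for the in-silico imaging experiments: an orientation
#' preference map, a per-pixel tuning amplitude (dF/F units), a baseline
#' fluorescence image and a sparse vasculature mask that locally darkens the
#' baseline.
#'
#' @param shape map size in pixels.
#' @param pixel_pitch_obj object-plane pixel pitch in micrometres.
#' @param column_periodicity column periodicity in cycles/mm.
#' @param tuning_amp peak orientation-tuned response amplitude (dF/F).
#' @param baseline baseline fluorescence (sensor-scale counts).
#' @param vessel_frac approximate area fraction covered by vessels.
#' @param seed integer seed.
#' @return object of class `cortex_phantom` with fields `pref_map`,
#'   `tuning_amp`, `baseline`, `vasculature`, `column_periodicity`,
#'   `pixel_pitch_obj`.
#' @export
cortex_phantom <- function(shape = 256, pixel_pitch_obj = 20,
                           column_periodicity = 1.2, tuning_amp = 0.03,
                           baseline = 100, vessel_frac = 0.03, seed = 1L) {
  if (length(shape) == 1) shape <- c(shape, shape)
  om <- generate_orientation_map(shape, pixel_pitch_obj, column_periodicity,
                                 seed = seed)
  # vasculature: thresholded smooth noise ridges (coarser than the columns)
  vas <- with_seed(seed + 1L, {
    n <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
    fy <- fft_freq(shape[1]); fx <- fft_freq(shape[2])
    r <- sqrt(outer(fy^2, fx^2, "+"))
    lp <- exp(-(r / 0.02)^2)
    sm <- Re(ifft2(fft2(n) * lp))
    q <- stats::quantile(abs(sm - stats::median(sm)), 1 - vessel_frac)
    abs(sm - stats::median(sm)) > q
  })
  base <- matrix(baseline, shape[1], shape[2])
  base[vas] <- baseline * 0.6
  amp <- matrix(tuning_amp, shape[1], shape[2])
  amp[vas] <- 0
  structure(list(pref_map = om$pref_map, tuning_amp = amp, baseline = base,
                 vasculature = vas, column_periodicity = column_periodicity,
                 pixel_pitch_obj = pixel_pitch_obj, strength = om$strength,
                 seed = seed),
            class = "cortex_phantom")
}

#' @export
print.cortex_phantom <- function(x, ...) {
  cat(sprintf("<cortex_phantom> %d x %d px (%.2f x %.2f mm), columns %.2g cycles/mm\n",
              nrow(x$pref_map), ncol(x$pref_map),
              nrow(x$pref_map) * x$pixel_pitch_obj * 1e-3,
              ncol(x$pref_map) * x$pixel_pitch_obj * 1e-3,
              x$column_periodicity))
  cat(sprintf("  tuning amp (max dF/F) %.3g, baseline %.3g counts, %.1f%% vessels\n",
              max(x$tuning_amp), max(x$baseline), 100 * mean(x$vasculature)))
  invisible(x)
}

#' Stimulus protocol
#'
#' Trial timing of the flashed-grating protocol: gratings flashed at
#' `stim_freq` (100 ms ON, 150 ms OFF at 4 Hz) for `cycles_per_trial`
#' cycles, recorded at `frame_rate`.
#'
#' @param orientations stimulus orientations in degrees.
#' @param stim_freq flash frequency in Hz.
#' @param on_ms,off_ms flash ON/OFF durations; must sum to `1000/stim_freq`.
#' @param cycles_per_trial flashes per trial.
#' @param frame_rate acquisition rate in Hz.
#' @param pre_onset_ms recorded baseline before stimulus onset (>= 200 ms
#'   is required by the blank-subtraction residual window).
#' @param trials_per_condition,blank_trials repeats per condition and number
#'   of blank fixation trials.
#' @param seed integer seed for trial-level randomness.
#' @return object of class `stimulus_protocol`; `n_frames` and
#'   `onset_frame` are derived fields.
#' @export
stimulus_protocol <- function(orientations = c(0, 30, 60, 90, 120, 150),
                              stim_freq = 4, on_ms = 100, off_ms = 150,
                              cycles_per_trial = 4, frame_rate = 20,
                              pre_onset_ms = 500, trials_per_condition = 10,
                              blank_trials = 10, seed = 1L) {
  if (abs(on_ms + off_ms - 1000 / stim_freq) > 1e-9)
    stop("on_ms + off_ms must equal 1000 / stim_freq", call. = FALSE)
  stim_ms <- cycles_per_trial * 1000 / stim_freq
  frame_ms <- 1000 / frame_rate
  if (abs(pre_onset_ms %% frame_ms) > 1e-9 || abs(stim_ms %% frame_ms) > 1e-9)
    stop("pre-onset and stimulus durations must be whole frames", call. = FALSE)
  onset_frame <- as.integer(round(pre_onset_ms / frame_ms)) + 1L
  n_frames <- as.integer(round((pre_onset_ms + stim_ms) / frame_ms))
  structure(list(orientations = orientations, stim_freq = stim_freq,
                 on_ms = on_ms, off_ms = off_ms,
                 cycles_per_trial = cycles_per_trial, frame_rate = frame_rate,
                 pre_onset_ms = pre_onset_ms,
                 trials_per_condition = trials_per_condition,
                 blank_trials = blank_trials, seed = seed,
                 onset_frame = onset_frame, n_frames = n_frames),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(paste0("<stimulus_protocol> %d orientations x %d trials + %d blanks; ",
                     "%g Hz flash (%g/%g ms) x %d cycles at %g Hz, %d frames/trial\n"),
              length(x$orientations), x$trials_per_condition, x$blank_trials,
              x$stim_freq, x$on_ms, x$off_ms, x$cycles_per_trial, x$frame_rate,
              x$n_frames))
  invisible(x)
}

# GCaMP6f-like impulse response (difference of exponentials), sampled at dt
# seconds and normalized to unit peak.
gcamp_kernel <- function(dt, tau_rise = 0.05, tau_decay = 0.4, n_tau = 6) {
  t <- seq(0, n_tau * tau_decay, by = dt)
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / max(k)
}

# Flash-train envelope convolved with the indicator kernel, sampled at the
# frame times of a trial (continuous-time convolution on a fine grid).
stim_envelope <- function(protocol, tau_rise = 0.05, tau_decay = 0.4) {
  dt <- 0.005
  total_s <- protocol$n_frames / protocol$frame_rate
  t <- seq(0, total_s - dt, by = dt)
  onset_s <- protocol$pre_onset_ms / 1000
  period <- 1 / protocol$stim_freq
  phase <- t - onset_s
  on <- phase >= 0 & phase < protocol$cycles_per_trial * period &
        (phase %% period) < protocol$on_ms / 1000
  k <- gcamp_kernel(dt, tau_rise, tau_decay)
  env <- stats::convolve(as.numeric(on), rev(k), type = "open")[seq_along(t)]
  env <- env / max(env)
  frame_idx <- round((seq_len(protocol$n_frames) - 0.5) / protocol$frame_rate / dt)
  env[pmin(pmax(frame_idx, 1), length(t))]
}

#' Generate one trial video at the object plane
#'
#' Per-pixel orientation-tuned response (cosine tuning, full modulation
#' depth) times the flash-train envelope convolved with a GCaMP6f-like
#' impulse response, on top of the baseline image; a global multiplicative
#' heartbeat sinusoid (2-3 Hz) emulates the dominant physiological artifact.
#' Shot/read noise can be applied here (object-plane noise) or downstream at
#' the sensor via [add_sensor_noise()].
#'
#' @param phantom a `cortex_phantom`.
#' @param protocol a `stimulus_protocol`.
#' @param condition stimulus orientation in degrees, or `"blank"`.
#' @param noise list with `heartbeat_freq` (Hz), `heartbeat_amp`
#'   (fractional), `photon_scale`, `read_sigma` (passed to
#'   [add_sensor_noise()]; `photon_scale = Inf`, `read_sigma = 0` leaves the
#'   video noiseless), `heartbeat_locked` (phase-lock trial start to the
#'   artifact, emulating heartbeat-triggered acquisition).
#' @param seed integer seed (heartbeat phase and sensor noise).
#' @param tau_rise,tau_decay GCaMP kernel time constants in seconds.
#' @return 3-D array `(time, y, x)` of object-plane fluorescence.
#' @export
generate_trial_video <- function(phantom, protocol, condition,
                                 noise = list(), seed = 1L,
                                 tau_rise = 0.05, tau_decay = 0.4) {
  blank <- identical(condition, "blank")
  if (!blank && !is.numeric(condition))
    stop("`condition` must be an orientation in degrees or \"blank\"",
         call. = FALSE)
  nz <- utils::modifyList(list(heartbeat_freq = 2.5, heartbeat_amp = 0,
                               photon_scale = Inf, read_sigma = 0,
                               heartbeat_locked = FALSE), noise)
  ny <- nrow(phantom$pref_map); nx <- ncol(phantom$pref_map)
  nt <- protocol$n_frames
  resp <- if (blank) matrix(0, ny, nx) else
    phantom$tuning_amp * (1 + cospi(2 * (phantom$pref_map - condition) / 180)) / 2
  env <- stim_envelope(protocol, tau_rise, tau_decay)
  hb_phase <- if (nz$heartbeat_locked) 0 else
    with_seed(seed, stats::runif(1, 0, 2 * pi))
  tt <- (seq_len(nt) - 1) / protocol$frame_rate
  hb <- 1 + nz$heartbeat_amp * sin(2 * pi * nz$heartbeat_freq * tt + hb_phase)
  video <- array(0, dim = c(nt, ny, nx))
  for (f in seq_len(nt))
    video[f, , ] <- phantom$baseline * (1 + resp * env[f]) * hb[f]
  if (is.finite(nz$photon_scale) || nz$read_sigma > 0)
    video <- add_sensor_noise(video, photon_scale = nz$photon_scale,
                              read_sigma = nz$read_sigma, seed = seed + 1L,
                              bit_depth = NULL)
  video
}

#' Line width of a USAF-1951 element
#'
#' The standard chart formula: `element` `e` of `group` `g` has
#' `2^(g + (e-1)/6)` line pairs per mm, so the line width is
#' `500 / 2^(g + (e-1)/6)` micrometres.
#'
#' @param group chart group (may be negative).
#' @param element element within the group, 1-6.
#' @return line width in micrometres.
#' @export
usaf_linewidth <- function(group, element) {
  if (any(element < 1 | element > 6))
    stop("`element` must be in 1..6", call. = FALSE)
  500 / 2^(group + (element - 1) / 6)
}

#' Synthetic USAF-1951 resolution target
#'
#' Renders the three-bar elements of the requested groups as bright bars on
#' a dark background (the fluorescent-negative-target counterpart): each
#' element is three horizontal plus three vertical bars of width `w` and
#' length `5 w`, spaced `w` apart.  Elements whose bars would be narrower
#' than 2 pixels at the given pitch are omitted with a warning.  The layout
#' is a simple grid of elements (not the spiral chart layout); bar geometry
#' is what matters for resolution phantoms.
#'
#' @param pixel_pitch_obj object-plane pixel pitch in micrometres.
#' @param groups integer vector of chart groups to render.
#' @param elements elements per group (subset of 1-6).
#' @return binary matrix (1 = bright bar) with attribute `pixel_pitch_obj`.
#' @export
generate_usaf_target <- function(pixel_pitch_obj, groups = 2:3, elements = 1:6) {
  cells <- list()
  omitted <- character()
  for (g in groups) for (e in elements) {
    w <- usaf_linewidth(g, e) / pixel_pitch_obj   # px
    wi <- round(w)
    if (wi < 2) { omitted <- c(omitted, sprintf("g%d e%d", g, e)); next }
    len <- 5L * wi
    # horizontal bars block: 3 bars of (wi x len) separated by wi
    hb <- matrix(0L, 5L * wi, len)
    for (b in 0:2) hb[(2 * b * wi + 1):(2 * b * wi + wi), ] <- 1L
    # vertical bars block
    vb <- matrix(0L, len, 5L * wi)
    for (b in 0:2) vb[, (2 * b * wi + 1):(2 * b * wi + wi)] <- 1L
    gap <- matrix(0L, nrow(hb), wi * 2L)
    cell <- cbind(hb, gap, rbind(vb, matrix(0L, nrow(hb) - nrow(vb), ncol(vb))))
    cells[[length(cells) + 1L]] <- cell
  }
  if (length(omitted))
    warning("elements unresolvable at this pitch, omitted: ",
            paste(omitted, collapse = ", "))
  if (!length(cells)) stop("no resolvable elements at this pitch", call. = FALSE)
  pad <- max(vapply(cells, nrow, 1L))
  wtot <- vapply(cells, ncol, 1L)
  margin <- 4L
  out <- matrix(0L, pad + 2L * margin,
                sum(wtot) + margin * (length(cells) + 1L))
  x0 <- margin
  for (k in seq_along(cells)) {
    cl <- cells[[k]]
    out[(margin + 1):(margin + nrow(cl)), (x0 + 1):(x0 + ncol(cl))] <- cl
    x0 <- x0 + ncol(cl) + margin
  }
  attr(out, "pixel_pitch_obj") <- pixel_pitch_obj
  out
}
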