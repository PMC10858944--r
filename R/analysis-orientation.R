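# Orientation-column mapping and decoding: stimulus-harmonic amplitude
# maps, RMS region selection, spatial bandpass, d-prime maps, the linear
# d-prime-weighted decoder with cross-validation, pairwise map
# correlations, vector-summation composite maps, map comparison and the
# label-shuffle null.

#' First-harmonic amplitude map
#'
#' Per-pixel Fourier amplitude of the time course at the stimulus frequency,
#' scaled so a pure sinusoid of amplitude `A` returns `A`:
#' `(2/N) |sum_t x_t exp(-i 2 pi f t / fs)|`.  When the frequency does not
#' fall on the DFT grid of the supplied window the nearest bin is used with
#' a warning (trial lengths are normally chosen so 4 Hz is exact at 20 Hz).
#'
#' @param video 3-D array `(time, y, x)`; pass the response window only.
#' @param stim_freq stimulus frequency in Hz.
#' @param frame_rate acquisition rate in Hz.
#' @return matrix `(y, x)` of amplitudes.
#' @export
harmonic_amplitude <- function(video, stim_freq = 4, frame_rate = 20) {
  n <- dim(video)[1]
  if (stim_freq >= frame_rate / 2)
    stop("stimulus frequency must be below Nyquist", call. = FALSE)
  if (n < 2 * frame_rate / stim_freq)
    stop("need at least two stimulus cycles", call. = FALSE)
  kf <- stim_freq * n / frame_rate
  if (abs(kf - round(kf)) > 1e-9) {
    warning(sprintf("%g Hz is not on the DFT grid of %d frames; using bin %d",
                    stim_freq, n, round(kf)))
    kf <- round(kf)
  }
  e <- exp(-2i * pi * kf * (0:(n - 1)) / n)
  flat <- matrix(video, nrow = n)
  amp <- Mod(matrix(e, 1) %*% flat) * 2 / n
  matrix(amp, dim(video)[2], dim(video)[3])
}

#' RMS region-of-interest mask
#'
#' Root-mean-square of the per-condition amplitude maps at each pixel;
#' the ROI keeps pixels whose RMS exceeds `threshold_frac` of the maximum
#' (the in-vivo rule keeps RMS greater than one-third of the maximum).
#'
#' @param amplitude_maps list of matrices (one per condition).
#' @param threshold_frac threshold as a fraction of the RMS maximum.
#' @return logical matrix.
#' @export
rms_roi <- function(amplitude_maps, threshold_frac = 1 / 3) {
  if (!length(amplitude_maps)) stop("need at least one map", call. = FALSE)
  rms <- sqrt(Reduce(`+`, lapply(amplitude_maps, function(m) m^2)) /
              length(amplitude_maps))
  if (max(rms) == 0) stop("all-zero amplitude maps", call. = FALSE)
  rms > threshold_frac * max(rms)
}

# radial raised-cosine annulus response at radius r (cycles/mm)
bandpass_response <- function(r, low, high, taper = 0.1) {
  h <- numeric(length(r))
  lo1 <- low - taper / 2; lo2 <- low + taper / 2
  hi1 <- high - taper / 2; hi2 <- high + taper / 2
  h[r >= lo2 & r <= hi1] <- 1
  ramp <- r > lo1 & r < lo2
  h[ramp] <- 0.5 * (1 - cos(pi * (r[ramp] - lo1) / taper))
  ramp <- r > hi1 & r < hi2
  h[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - hi1) / taper))
  h
}

#' Spatial bandpass filter
#'
#' Annular Fourier-domain filter keeping radial spatial frequencies between
#' `low` and `high` cycles/mm (defaults bracketing the ~1.2 cycles/mm column
#' periodicity), removing non-orientation-selective low-frequency responses
#' and high-frequency noise.  Edges are raised-cosine tapered over
#' `taper` cycles/mm (set `hard = TRUE` for a hard annulus).
#'
#' @param map numeric matrix.
#' @param low,high band edges in cycles/mm.
#' @param pixel_pitch_obj object-plane pixel pitch in micrometres.
#' @param taper taper width in cycles/mm.
#' @param hard use a hard-edged annulus instead of the taper.
#' @return filtered matrix (real part).
#' @export
bandpass_spatial <- function(map, low = 0.8, high = 2.5, pixel_pitch_obj = 20,
                             taper = 0.1, hard = FALSE) {
  nyq <- 1 / (2 * pixel_pitch_obj * 1e-3)
  if (high >= nyq) stop("`high` must be below Nyquist at this pitch", call. = FALSE)
  fy <- fft_freq(nrow(map), pixel_pitch_obj * 1e-3)
  fx <- fft_freq(ncol(map), pixel_pitch_obj * 1e-3)
  r <- sqrt(outer(fy^2, fx^2, "+"))
  H <- if (hard) (r >= low & r <= high) * 1
       else matrix(bandpass_response(as.vector(r), low, high, taper),
                   nrow(map), ncol(map))
  Re(ifft2(fft2(map) * H))
}

#' Pixel-wise discriminability (d-prime) map
#'
#' `(m0 - m90) / sqrt((s0^2 + s90^2) / 2)` element-wise; pixels with zero
#' pooled SD return 0 and their count is attached as attribute `n_zero_sd`.
#'
#' @param m0,m90 condition mean-response maps.
#' @param s0,s90 condition SD maps (across trials).
#' @return d-prime matrix.
#' @export
dprime_map <- function(m0, m90, s0, s90) {
  stopifnot(identical(dim(m0), dim(m90)), identical(dim(s0), dim(s90)),
            identical(dim(m0), dim(s0)))
  pooled <- sqrt((s0^2 + s90^2) / 2)
  out <- (m0 - m90) / pooled
  zero <- pooled == 0
  out[zero] <- 0
  attr(out, "n_zero_sd") <- sum(zero)
  out
}

# stack a list of maps into (trial, pixel) rows restricted to the ROI
roi_rows <- function(maps, roi_mask) {
  do.call(rbind, lapply(maps, function(m) as.vector(m[roi_mask])))
}

dprime_scalar <- function(a, b) {
  (mean(a) - mean(b)) / sqrt((stats::var(a) + stats::var(b)) / 2)
}

#' Linear d-prime-weighted orientation decoder
#'
#' Forms a per-trial decision variable by weighting each pixel's single-trial
#' response with the pixel-wise d-prime map and summing over the ROI, then
#' reports the discriminability of the two decision-variable distributions
#' (difference of means over pooled SD).  With leave-one-out
#' cross-validation the weights for each trial are computed with that trial
#' held out of its own condition, and the reported d-prime uses held-out
#' decision variables only.
#'
#' @param trial_maps_0,trial_maps_90 lists of per-trial response maps for
#'   the two orientations (0 and 90 degrees in the in-vivo protocol).
#' @param roi_mask logical matrix; `NULL` uses all pixels.
#' @param cv `"loo"` (leave-one-trial-out) or `"none"`.
#' @param weights optional fixed weight map (e.g. a population d-prime map);
#'   implies `cv = "none"`.
#' @return object of class `decoder_result`: `dv0`, `dv90`, `dprime_dv`,
#'   `cv_scheme`.
#' @export
decode_orientation <- function(trial_maps_0, trial_maps_90, roi_mask = NULL,
                               cv = c("loo", "none"), weights = NULL) {
  cv <- if (!is.null(weights)) "none" else match.arg(cv)
  if (is.null(roi_mask))
    roi_mask <- matrix(TRUE, nrow(trial_maps_0[[1]]), ncol(trial_maps_0[[1]]))
  n0 <- length(trial_maps_0); n90 <- length(trial_maps_90)
  min_n <- if (cv == "loo") 3L else 2L
  if (n0 < min_n || n90 < min_n)
    stop(sprintf("need at least %d trials per condition", min_n), call. = FALSE)
  X0 <- roi_rows(trial_maps_0, roi_mask)
  X90 <- roi_rows(trial_maps_90, roi_mask)

  dp_vec <- function(A, B) {
    m0 <- colMeans(A); m90 <- colMeans(B)
    s0 <- apply(A, 2, stats::sd); s90 <- apply(B, 2, stats::sd)
    pooled <- sqrt((s0^2 + s90^2) / 2)
    w <- (m0 - m90) / pooled
    w[pooled == 0] <- 0
    w
  }

  if (cv == "none") {
    w <- if (!is.null(weights)) as.vector(weights[roi_mask]) else dp_vec(X0, X90)
    dv0 <- as.vector(X0 %*% w)
    dv90 <- as.vector(X90 %*% w)
  } else {
    dv0 <- vapply(seq_len(n0), function(t) {
      sum(X0[t, ] * dp_vec(X0[-t, , drop = FALSE], X90))
    }, 0)
    dv90 <- vapply(seq_len(n90), function(t) {
      sum(X90[t, ] * dp_vec(X0, X90[-t, , drop = FALSE]))
    }, 0)
  }
  structure(list(dv0 = dv0, dv90 = dv90,
                 dprime_dv = dprime_scalar(dv0, dv90),
                 cv_scheme = if (cv == "loo") "leave-one-trial-out" else "none"),
            class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf("<decoder_result> d'_DV = %.3f (%d vs %d trials, cv: %s)\n",
              x$dprime_dv, length(x$dv0), length(x$dv90), x$cv_scheme))
  invisible(x)
}

# circular orientation difference modulo 180 degrees
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Pairwise correlations between single-orientation maps
#'
#' Pearson correlation of every unordered pair of maps over the ROI, with
#' the pair's stimulus orientation difference taken circularly modulo 180
#' degrees, averaged per unique difference.  For ideal cosine-tuned maps
#' the curve equals `cos(2 * delta)`.
#'
#' @param maps list of response maps.
#' @param orientations stimulus orientations in degrees, one per map.
#' @param roi_mask logical matrix; `NULL` uses all pixels.
#' @return data frame with `delta`, `r_mean`, `n_pairs`; the full pair table
#'   is attached as attribute `pairs`.
#' @export
pairwise_map_correlation <- function(maps, orientations, roi_mask = NULL) {
  if (length(maps) < 2) stop("need at least two maps", call. = FALSE)
  if (length(maps) != length(orientations))
    stop("one orientation per map required", call. = FALSE)
  if (is.null(roi_mask))
    roi_mask <- matrix(TRUE, nrow(maps[[1]]), ncol(maps[[1]]))
  vecs <- lapply(maps, function(m) as.vector(m[roi_mask]))
  pairs <- utils::combn(length(maps), 2)
  res <- data.frame(i = pairs[1, ], j = pairs[2, ],
                    delta = orientation_diff(orientations[pairs[1, ]],
                                             orientations[pairs[2, ]]),
                    r = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    a <- vecs[[pairs[1, k]]]; b <- vecs[[pairs[2, k]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning(sprintf("zero-variance map in pair (%d, %d); skipped",
                      pairs[1, k], pairs[2, k]))
      next
    }
    res$r[k] <- stats::cor(a, b)
  }
  ok <- !is.na(res$r)
  if (!any(ok)) {
    curve <- data.frame(delta = numeric(), r_mean = numeric(),
                        n_pairs = integer())
    attr(curve, "pairs") <- res
    return(curve)
  }
  curve <- stats::aggregate(r ~ delta, data = res[ok, ], FUN = mean)
  names(curve) <- c("delta", "r_mean")
  curve$n_pairs <- as.vector(table(res$delta[ok])[as.character(curve$delta)])
  attr(curve, "pairs") <- res
  curve
}

#' Composite orientation map by vector summation
#'
#' Per pixel, sums the single-orientation responses on the orientation
#' double-angle circle, \eqn{z = \sum_k R_k e^{i 2 \theta_k}}; the preferred
#' orientation is `arg(z) / 2` (mod 180 degrees) and the tuning strength is
#' `|z| / sum_k |R_k|` (0, with preference masked to 0, where the
#' denominator vanishes).
#'
#' @param single_maps list of per-orientation response maps.
#' @param orientations stimulus orientations in degrees, spanning `[0, 180)`.
#' @return list with `pref_map` (degrees in `[0, 180)`) and `magnitude_map`.
#' @export
composite_orientation_map <- function(single_maps, orientations) {
  if (length(single_maps) < 3)
    stop("need at least 3 orientations", call. = FALSE)
  z <- matrix(0 + 0i, nrow(single_maps[[1]]), ncol(single_maps[[1]]))
  denom <- matrix(0, nrow(z), ncol(z))
  for (k in seq_along(single_maps)) {
    z <- z + single_maps[[k]] * exp(2i * pi * orientations[k] / 180)
    denom <- denom + abs(single_maps[[k]])
  }
  pref <- ((Arg(z) %% (2 * pi)) / 2) * (180 / pi)
  mag <- matrix(0, nrow(z), ncol(z))
  ok <- denom > 0
  mag[ok] <- Mod(z)[ok] / denom[ok]
  # isotropic pixels: the vector sum cancels (up to roundoff) and the
  # preference is undefined; mask it to 0
  undef <- !ok | Mod(z) <= 1e-12 * denom
  pref[undef] <- 0
  mag[undef] <- 0
  list(pref_map = pref %% 180, magnitude_map = mag)
}

#' Correlation between two preferred-orientation maps
#'
#' Converts each map to `sin(2 * theta)` (a smooth `[-1, 1]` encoding of
#' orientation) and reports the Pearson correlation over the ROI.
#'
#' @param prefA,prefB preferred-orientation maps in degrees.
#' @param roi_mask logical matrix; `NULL` uses all pixels.
#' @return correlation coefficient.
#' @export
compare_maps <- function(prefA, prefB, roi_mask = NULL) {
  stopifnot(identical(dim(prefA), dim(prefB)))
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, nrow(prefA), ncol(prefA))
  a <- sinpi(2 * prefA[roi_mask] / 180)
  b <- sinpi(2 * prefB[roi_mask] / 180)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant converted map: correlation undefined", call. = FALSE)
  stats::cor(a, b)
}

#' Orientation-label shuffle null distribution
#'
#' Repeatedly permutes the orientation labels of the single-orientation
#' maps (uniform random permutation per shuffle, drawn with replacement
#' across shuffles), rebuilds the composite map, and correlates it with the
#' reference preferred-orientation map via [compare_maps()].
#'
#' Because the comparison encodes maps as `sin(2 * theta)`, two relabelings
#' reproduce the unshuffled comparison exactly for any real-valued response
#' maps: the identity, and the reflection `theta -> 90 - theta` (which maps
#' the composite field to minus its conjugate).  These encoding-equivalent
#' relabelings carry no information about label structure, so the sampled
#' null excludes them; forced `permutations` bypass the exclusion (e.g. to
#' check that the identity reproduces the unshuffled value).
#'
#' @param single_maps list of per-orientation response maps.
#' @param orientations stimulus orientations in degrees.
#' @param reference_pref_map reference preferred-orientation map (degrees).
#' @param n_shuffles number of relabelings (the in-vivo control uses 1500).
#' @param seed integer seed.
#' @param roi_mask logical matrix or `NULL`.
#' @param permutations optional integer matrix (`n_shuffles` x n maps) of
#'   forced label permutations (diagnostics; e.g. the identity).
#' @return list with `r` (all shuffle correlations), `min`, `max`, `mean`.
#' @export
shuffle_null <- function(single_maps, orientations, reference_pref_map,
                         n_shuffles = 1500, seed = 1L, roi_mask = NULL,
                         permutations = NULL) {
  if (n_shuffles < 1) stop("`n_shuffles` must be >= 1", call. = FALSE)
  m <- length(single_maps)
  perms <- if (!is.null(permutations)) permutations
           else with_seed(seed, {
    # relabelings whose sin(2 theta) encoding equals the unshuffled one
    equiv <- function(p) {
      all(orientations[p] %% 180 == orientations %% 180) ||
        all((orientations[p] %% 180) == ((90 - orientations) %% 180))
    }
    t(replicate(n_shuffles, {
      p <- sample.int(m)
      while (equiv(p)) p <- sample.int(m)
      p
    }))
  })
  r <- vapply(seq_len(nrow(perms)), function(s) {
    comp <- composite_orientation_map(single_maps, orientations[perms[s, ]])
    compare_maps(comp$pref_map, reference_pref_map, roi_mask)
  }, 0)
  list(r = r, min = min(r), max = max(r), mean = mean(r))
}

#' Orientation-mapping pipeline on a trial set
#'
#' The map-construction path of the orientation analysis in one call:
#' blank subtraction, per-condition trial averaging, first-harmonic
#' amplitude maps over the stimulus window, RMS ROI selection, spatial
#' bandpass, pairwise map correlations and the vector-summation composite
#' map.
#'
#' @param trials a `trial_set` with orientation-degree conditions plus
#'   blanks.
#' @param stim_freq stimulus frequency in Hz.
#' @param band band edges in cycles/mm.
#' @param pixel_pitch_obj object-plane pixel pitch in micrometres.
#' @param threshold_frac RMS ROI threshold fraction.
#' @return object of class `orientation_map_set`: `single_maps` (bandpassed,
#'   per orientation), `amplitude_maps` (raw), `orientations`, `roi_mask`,
#'   `corr_curve`, `pref_map`, `magnitude_map`.
#' @export
orientation_maps <- function(trials, stim_freq = 4, band = c(0.8, 2.5),
                             pixel_pitch_obj = 20, threshold_frac = 1 / 3) {
  st <- subtract_blank(trials)
  orientations <- sort(unique(as.numeric(st$condition)))
  d <- dim(st$videos[[1]])
  win <- st$onset_frame:d[1]
  amp_maps <- lapply(orientations, function(o) {
    sel <- which(as.numeric(st$condition) == o)
    avg <- array(0, d)
    for (t in sel) avg <- avg + st$videos[[t]]
    harmonic_amplitude(avg[win, , , drop = FALSE] / length(sel),
                       stim_freq, st$frame_rate)
  })
  roi <- rms_roi(amp_maps, threshold_frac)
  bp <- lapply(amp_maps, bandpass_spatial, low = band[1], high = band[2],
               pixel_pitch_obj = pixel_pitch_obj)
  curve <- pairwise_map_correlation(bp, orientations, roi)
  comp <- composite_orientation_map(bp, orientations)
  structure(list(single_maps = bp, amplitude_maps = amp_maps,
                 orientations = orientations, roi_mask = roi,
                 corr_curve = curve, pref_map = comp$pref_map,
                 magnitude_map = comp$magnitude_map),
            class = "orientation_map_set")
}

#' @export
print.orientation_map_set <- function(x, ...) {
  cat(sprintf("<orientation_map_set> %d orientations (%s deg), maps %d x %d px\n",
              length(x$orientations),
              paste(x$orientations, collapse = ", "),
              nrow(x$pref_map), ncol(x$pref_map)))
  cat(sprintf("  ROI %.1f%% of FOV; pairwise r: %s\n",
              100 * mean(x$roi_mask),
              paste(sprintf("%g deg: %.2f", x$corr_curve$delta,
                            x$corr_curve$r_mean), collapse = ", ")))
  invisible(x)
}

#' @export
plot.orientation_map_set <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  img <- x$pref_map
  graphics::image(t(img[nrow(img):1, ]), col = grDevices::hcl.colors(180, "Spectral"),
                  axes = FALSE, main = "preferred orientation")
  graphics::plot(x$corr_curve$delta, x$corr_curve$r_mean, type = "b",
                 xlab = "orientation difference (deg)", ylab = "mean Pearson r",
                 ylim = c(-1, 1), main = "pairwise map correlation")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
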