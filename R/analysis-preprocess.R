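# Trial preprocessing: the trial container, blank subtraction with
# pre-onset residual removal, dF/F, and rigid frame registration.

#' Trial set
#'
#' Collection of same-shaped trial videos with condition labels.
#'
#' @param videos list of 3-D arrays `(time, y, x)` (raw counts or dF/F).
#' @param condition vector of labels, one per trial: a stimulus position
#'   index, an orientation in degrees, or `"blank"`.
#' @param frame_rate acquisition rate in Hz.
#' @param onset_frame index of the first stimulus frame.
#' @return object of class `trial_set`.
#' @export
trial_set <- function(videos, condition, frame_rate = 20, onset_frame = 1L) {
  if (length(videos) != length(condition))
    stop("one condition label per trial required", call. = FALSE)
  d <- dim(videos[[1]])
  if (!all(vapply(videos, function(v) identical(dim(v), d), TRUE)))
    stop("all trials must have the same shape", call. = FALSE)
  structure(list(videos = videos, condition = as.character(condition),
                 frame_rate = frame_rate, onset_frame = as.integer(onset_frame)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$videos[[1]])
  tab <- table(x$condition)
  cat(sprintf("<trial_set> %d trials of %d frames (%d x %d px) at %g Hz, onset frame %d\n",
              length(x$videos), d[1], d[2], d[3], x$frame_rate, x$onset_frame))
  cat("  conditions:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Blank subtraction with pre-onset residual removal
#'
#' Subtracts the average blank-trial time course (per pixel, per frame) from
#' every stimulus trial, then removes each trial's mean residual over the
#' 200 ms window immediately before stimulus onset.  This cancels shared
#' slow fluctuations (heartbeat-locked hemodynamics) and re-references every
#' corrected trial to a zero pre-onset baseline.
#'
#' @param trials a `trial_set` containing at least one `"blank"` trial and
#'   at least 200 ms of pre-onset frames.
#' @param pre_ms residual window length in ms before onset (default 200).
#' @return a `trial_set` of the corrected stimulus trials (blanks dropped).
#' @export
subtract_blank <- function(trials, pre_ms = 200) {
  is_blank <- trials$condition == "blank"
  if (!any(is_blank)) stop("no blank trials", call. = FALSE)
  k <- as.integer(round(pre_ms / 1000 * trials$frame_rate))
  if (k < 1 || trials$onset_frame <= k)
    stop(sprintf("need at least %g ms of pre-onset frames", pre_ms),
         call. = FALSE)
  d <- dim(trials$videos[[1]])
  blank_avg <- array(0, d)
  for (v in trials$videos[is_blank]) blank_avg <- blank_avg + v
  blank_avg <- blank_avg / sum(is_blank)
  pre <- (trials$onset_frame - k):(trials$onset_frame - 1L)
  corrected <- lapply(trials$videos[!is_blank], function(v) {
    v <- v - blank_avg
    resid <- apply(v[pre, , , drop = FALSE], c(2, 3), mean)
    sweep_t(v, resid)
  })
  trial_set(corrected, trials$condition[!is_blank], trials$frame_rate,
            trials$onset_frame)
}

# subtract a (y, x) image from every frame of a (t, y, x) video
sweep_t <- function(video, img) {
  nt <- dim(video)[1]
  video - aperm(array(img, dim = c(dim(img), nt)), c(3, 1, 2))
}

#' Fractional fluorescence change (dF/F)
#'
#' `(F - F0) / F0` with `F0` the per-pixel mean over the baseline window.
#' Pixels with a nonpositive baseline are masked to `NaN`; their count is
#' attached as attribute `n_masked`.
#'
#' @param video 3-D array `(time, y, x)`.
#' @param baseline_window frame indices defining `F0`.
#' @return dF/F video of the same shape.
#' @export
dff <- function(video, baseline_window) {
  f0 <- apply(video[baseline_window, , , drop = FALSE], c(2, 3), mean)
  bad <- f0 <= 0
  f0[bad] <- NA_real_
  nt <- dim(video)[1]
  f0rep <- aperm(array(f0, dim = c(dim(f0), nt)), c(3, 1, 2))
  out <- (video - f0rep) / f0rep
  attr(out, "n_masked") <- sum(bad)
  out
}

# cross-correlation surface between two images via FFT (circular);
# returns the complex cross-power spectrum too, for subpixel refinement
xcorr_surface <- function(frame, template) {
  Fa <- fft2(frame); Fb <- fft2(template)
  cp <- Fa * Conj(Fb)
  list(surface = Re(ifft2(cp)), cross_power = cp)
}

# evaluate the inverse DFT of `cp` on an upsampled local grid around
# (dy0, dx0) (shifts in pixels), returning the refined peak location
upsampled_peak <- function(cp, dy0, dx0, upsample, halfwidth = 1.5) {
  ny <- nrow(cp); nx <- ncol(cp)
  wy <- 2 * pi * fft_freq(ny)   # radians per pixel of shift
  wx <- 2 * pi * fft_freq(nx)
  dys <- dy0 + seq(-halfwidth, halfwidth, by = 1 / upsample)
  dxs <- dx0 + seq(-halfwidth, halfwidth, by = 1 / upsample)
  Ey <- exp(1i * outer(dys, wy))          # n_dy x ny
  Ex <- exp(1i * outer(wx, dxs))          # nx x n_dx
  s <- Re(Ey %*% cp %*% Ex)
  pk <- which(s == max(s), arr.ind = TRUE)[1, ]
  c(dys[pk[1]], dxs[pk[2]])
}

#' Rigid registration of a video to a template
#'
#' Per-frame rigid translation estimated from the cross-correlation peak
#' (FFT-based), refined on an `upsample`-times finer grid around the integer
#' peak; frames are shifted back by Fourier phase shifting.  Displacements
#' are reported in micrometres along both axes when a pixel pitch is given.
#' Frames whose correlation peak sits on the border of the search range are
#' flagged.
#'
#' @param video 3-D array `(time, y, x)`.
#' @param template matrix of the frame size (e.g. a vascular reference
#'   image captured before release).
#' @param upsample subpixel refinement factor (1 = integer shifts).
#' @param pixel_pitch_obj pixel pitch in micrometres (for the displacement
#'   units); `1` reports pixels.
#' @return list with `displacements` (`n x 2` matrix, um, y/x),
#'   `corrected` (video), `flagged` (logical per frame).
#' @export
register_frames <- function(video, template, upsample = 10,
                            pixel_pitch_obj = 1) {
  d <- dim(video)
  if (!identical(d[2:3], dim(template)))
    stop("template must match the frame size", call. = FALSE)
  ny <- d[2]; nx <- d[3]
  disp <- matrix(0, d[1], 2)
  flagged <- logical(d[1])
  corrected <- video
  wy <- 2 * pi * fft_freq(ny); wx <- 2 * pi * fft_freq(nx)
  for (f in seq_len(d[1])) {
    xc <- xcorr_surface(matrix(video[f, , ], ny, nx), template)
    pk <- which(xc$surface == max(xc$surface), arr.ind = TRUE)[1, ]
    dy <- pk[1] - 1L; dx <- pk[2] - 1L
    if (dy > ny / 2) dy <- dy - ny
    if (dx > nx / 2) dx <- dx - nx
    flagged[f] <- abs(dy) >= floor(ny / 2) || abs(dx) >= floor(nx / 2)
    if (upsample > 1) {
      pk2 <- upsampled_peak(xc$cross_power, dy, dx, upsample)
      dy <- pk2[1]; dx <- pk2[2]
    }
    disp[f, ] <- c(dy, dx)
    # shift the frame back by (-dy, -dx) via Fourier phase
    ph <- exp(1i * outer(wy * dy, rep(1, nx))) *
          exp(1i * outer(rep(1, ny), wx * dx))
    corrected[f, , ] <- Re(ifft2(fft2(matrix(video[f, , ], ny, nx)) * ph))
  }
  list(displacements = disp * pixel_pitch_obj, corrected = corrected,
       flagged = flagged)
}

#' Retinotopic position tuning
#'
#' Blank-subtracts the trials, averages the response of each region of
#' interest over the stimulus window and across repeats, and fits a 1-D
#' Gaussian (amplitude, center, width, offset) to response versus stimulus
#' position per ROI.  The fitted center is the ROI's preferred visual-field
#' position.  ROIs are squares laid out along the horizontal midline of the
#' field of view, mirroring the six 0.3 x 0.3 mm boxes spaced ~0.37 mm of
#' the in-vivo analysis.
#'
#' @param trials a `trial_set` whose stimulus conditions are numeric
#'   positions in degrees of visual angle (plus blanks).
#' @param roi_size,roi_spacing,n_roi ROI geometry in mm.
#' @param pixel_pitch_obj object-plane pixel pitch in micrometres.
#' @param response_window frame indices (relative to the video) averaged as
#'   the response; default onset to onset + 1 s.
#' @return object of class `tuning_fit`: `responses` (ROI x condition
#'   matrix), `positions`, `fits` (per-ROI coefficient list:
#'   amplitude/center/width/offset or `NULL`), `flagged` (fit failures),
#'   `roi_centers_mm`.
#' @export
position_tuning <- function(trials, roi_size = 0.3, roi_spacing = 0.37,
                            n_roi = 6, pixel_pitch_obj = 20,
                            response_window = NULL) {
  st <- subtract_blank(trials)
  positions <- sort(unique(as.numeric(st$condition)))
  if (length(positions) < 3) stop("need >= 3 stimulus positions", call. = FALSE)
  d <- dim(st$videos[[1]])
  if (is.null(response_window)) {
    w1 <- st$onset_frame
    w2 <- min(d[1], st$onset_frame + as.integer(st$frame_rate) - 1L)
    response_window <- w1:w2
  }
  px_mm <- 1e3 / pixel_pitch_obj           # pixels per mm
  half <- max(1L, round(roi_size / 2 * px_mm))
  row0 <- round(d[2] / 2)
  total_w <- (n_roi - 1) * roi_spacing * px_mm
  cols <- round(d[3] / 2 + seq(-total_w / 2, total_w / 2, length.out = n_roi))
  roi_of <- function(cc) {
    list(rows = max(1, row0 - half):min(d[2], row0 + half - 1),
         cols = max(1, cc - half):min(d[3], cc + half - 1))
  }
  resp <- matrix(0, n_roi, length(positions),
                 dimnames = list(NULL, format(positions)))
  for (j in seq_along(positions)) {
    sel <- which(as.numeric(st$condition) == positions[j])
    avg <- array(0, d)
    for (t in sel) avg <- avg + st$videos[[t]]
    avg <- avg / length(sel)
    for (r in seq_len(n_roi)) {
      roi <- roi_of(cols[r])
      resp[r, j] <- mean(avg[response_window, roi$rows, roi$cols])
    }
  }
  fits <- vector("list", n_roi)
  flagged <- logical(n_roi)
  for (r in seq_len(n_roi)) {
    fits[r] <- list(fit_gaussian_1d(positions, resp[r, ]))
    flagged[r] <- is.null(fits[[r]])
  }
  structure(list(responses = resp, positions = positions, fits = fits,
                 flagged = flagged,
                 roi_centers_mm = (cols - d[3] / 2) / px_mm),
            class = "tuning_fit")
}

# least-squares 1D Gaussian a * exp(-(x - mu)^2 / (2 sigma^2)) + c;
# returns NULL on failure or a degenerate (flat) profile
fit_gaussian_1d <- function(x, y) {
  if (max(y) - min(y) <= .Machine$double.eps * max(abs(y), 1)) return(NULL)
  st <- list(a = max(y) - min(y), mu = x[which.max(y)],
             sigma = diff(range(x)) / 4, c = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)) + c,
                      start = st, data = data.frame(x = x, y = y),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- as.list(stats::coef(fit))
  cf$sigma <- abs(cf$sigma)
  if (cf$sigma <= 0) return(NULL)
  if (cf$mu < min(x) - diff(range(x)) || cf$mu > max(x) + diff(range(x)))
    return(NULL)
  cf$residuals <- stats::resid(fit)
  cf
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat(sprintf("<tuning_fit> %d ROIs x %d positions (%s deg)\n",
              nrow(x$responses), length(x$positions),
              paste(range(x$positions), collapse = " to ")))
  for (r in seq_len(nrow(x$responses))) {
    if (x$flagged[r]) cat(sprintf("  ROI %d: fit flagged\n", r))
    else cat(sprintf("  ROI %d: peak %.3f deg, width %.3f, amp %.3g\n",
                     r, x$fits[[r]]$mu, x$fits[[r]]$sigma, x$fits[[r]]$a))
  }
  invisible(x)
}
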