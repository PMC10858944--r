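# Contour phase-mask design: Perlin-noise contour targets, Canny edge
# extraction, angular-spectrum propagation, and transform-type phase
# retrieval with fabrication-step height quantization.

#' Gradient-lattice Perlin noise
#'
#' Classic two-dimensional Perlin noise: random unit gradients on a square
#' lattice, quintic fade interpolation of the corner dot products, rescaled
#' so values lie in \eqn{[-1, 1]}.  The lattice spacing (`feature_scale`)
#' sets the characteristic feature size of the field in physical units.
#'
#' @param shape integer vector of length 2, output size in pixels (rows, cols).
#' @param pixel_pitch pixel pitch in micrometres.
#' @param feature_scale lattice spacing in micrometres; must be at least
#'   `2 * pixel_pitch` so features are resolvable.
#' @param seed integer seed; identical seed and parameters give a
#'   bit-identical field.
#' @param gradients optional array `(n_row_nodes, n_col_nodes, 2)` of lattice
#'   gradients, overriding the seeded random unit vectors (used for
#'   reproducibility experiments; e.g. all-zero gradients give a zero field).
#' @return object of class `noise_field`: list with `values` (matrix in
#'   \eqn{[-1,1]}), `pixel_pitch`, `feature_scale`, `seed`.
#' @export
generate_perlin_noise <- function(shape, pixel_pitch, feature_scale, seed = 1L,
                                  gradients = NULL) {
  if (length(shape) == 1) shape <- c(shape, shape)
  shape <- as.integer(shape)
  if (any(shape <= 0)) stop("`shape` must be positive", call. = FALSE)
  stopifnot_positive(pixel_pitch, "pixel_pitch")
  stopifnot_positive(feature_scale, "feature_scale")
  if (feature_scale < 2 * pixel_pitch)
    stop("`feature_scale` must be >= 2 * pixel_pitch", call. = FALSE)

  # pixel coordinates in lattice units
  yl <- (seq_len(shape[1]) - 1) * pixel_pitch / feature_scale
  xl <- (seq_len(shape[2]) - 1) * pixel_pitch / feature_scale
  i0 <- floor(yl); j0 <- floor(xl)
  fy <- yl - i0; fx <- xl - j0
  ni <- max(i0) + 2L; nj <- max(j0) + 2L

  if (is.null(gradients)) {
    gradients <- with_seed(seed, {
      ang <- matrix(stats::runif(ni * nj, 0, 2 * pi), ni, nj)
      array(c(cos(ang), sin(ang)), dim = c(ni, nj, 2))
    })
  } else if (!identical(dim(gradients)[1:2] >= c(ni, nj), c(TRUE, TRUE))) {
    stop(sprintf("`gradients` must be at least %d x %d x 2", ni, nj),
         call. = FALSE)
  }

  fade <- function(t) t^3 * (t * (t * 6 - 15) + 10)
  uy <- fade(fy); ux <- fade(fx)

  # corner dot products, vectorized over the full image
  FY <- matrix(fy, shape[1], shape[2])
  FX <- matrix(fx, shape[1], shape[2], byrow = TRUE)
  corner <- function(di, dj) {
    idx <- cbind(rep(i0 + 1L + di, shape[2]),
                 rep(j0 + 1L + dj, each = shape[1]))
    gy <- matrix(gradients[cbind(idx, 1L)], shape[1], shape[2])
    gx <- matrix(gradients[cbind(idx, 2L)], shape[1], shape[2])
    gy * (FY - di) + gx * (FX - dj)
  }
  n00 <- corner(0L, 0L); n10 <- corner(1L, 0L)
  n01 <- corner(0L, 1L); n11 <- corner(1L, 1L)

  UY <- matrix(uy, shape[1], shape[2])
  UX <- matrix(ux, shape[1], shape[2], byrow = TRUE)
  vals <- (n00 * (1 - UY) + n10 * UY) * (1 - UX) +
          (n01 * (1 - UY) + n11 * UY) * UX
  # classic 2D Perlin is bounded by sqrt(2)/2; rescale into [-1, 1]
  vals <- vals * sqrt(2)
  vals[vals > 1] <- 1; vals[vals < -1] <- -1

  structure(list(values = vals, pixel_pitch = pixel_pitch,
                 feature_scale = feature_scale, seed = seed),
            class = "noise_field")
}

#' @export
print.noise_field <- function(x, ...) {
  cat(sprintf("<noise_field> %d x %d px, pitch %g um, feature scale %g um, seed %s\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch, x$feature_scale,
              format(x$seed)))
  invisible(x)
}

# Separable Gaussian smoothing with reflective boundaries.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  reflect_idx <- function(n) {
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
    idx
  }
  smooth1 <- function(m) {   # filter along rows (dimension 1)
    ext <- m[reflect_idx(nrow(m)), , drop = FALSE]
    out <- matrix(0, nrow(m), ncol(m))
    for (s in seq_along(k)) out <- out + k[s] * ext[s:(s + nrow(m) - 1), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(img))))
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, four-sector non-maximum suppression
#' and hysteresis thresholding with thresholds given as fractions of the
#' maximum gradient magnitude.
#'
#' @param img numeric matrix.
#' @param low_frac,high_frac hysteresis thresholds as fractions of the
#'   maximum gradient magnitude; `0 < low_frac < high_frac <= 1`.
#' @param sigma Gaussian smoothing width in pixels.
#' @return logical matrix of edge pixels (1-px border is always `FALSE`).
#' @export
canny_edges <- function(img, low_frac = 0.1, high_frac = 0.3, sigma = 1) {
  if (!(low_frac > 0 && low_frac < high_frac && high_frac <= 1))
    stop("need 0 < low_frac < high_frac <= 1", call. = FALSE)
  ny <- nrow(img); nx <- ncol(img)
  sm <- gaussian_smooth(img, sigma)
  # Sobel gradients (gy: down rows, gx: across cols), zero on the border
  gy <- matrix(0, ny, nx); gx <- matrix(0, ny, nx)
  ri <- 2:(ny - 1); ci <- 2:(nx - 1)
  gy[ri, ci] <- (sm[ri + 1, ci - 1] + 2 * sm[ri + 1, ci] + sm[ri + 1, ci + 1]) -
                (sm[ri - 1, ci - 1] + 2 * sm[ri - 1, ci] + sm[ri - 1, ci + 1])
  gx[ri, ci] <- (sm[ri - 1, ci + 1] + 2 * sm[ri, ci + 1] + sm[ri + 1, ci + 1]) -
                (sm[ri - 1, ci - 1] + 2 * sm[ri, ci - 1] + sm[ri + 1, ci - 1])
  mag <- sqrt(gy^2 + gx^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, ny, nx))

  # quantize gradient direction into 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx)            # (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:E-W, 1:NE-SW, 2:N-S, 3:NW-SE
  nms <- matrix(FALSE, ny, nx)
  off <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  for (s in 0:3) {
    d <- off[[as.character(s)]]
    sel <- sector == s & mag > 0
    sel[c(1, ny), ] <- FALSE; sel[, c(1, nx)] <- FALSE
    if (!any(sel)) next
    idx <- which(sel, arr.ind = TRUE)
    m0 <- mag[idx]
    m1 <- mag[cbind(idx[, 1] + d[1], idx[, 2] + d[2])]
    m2 <- mag[cbind(idx[, 1] - d[1], idx[, 2] - d[2])]
    keep <- m0 >= m1 & m0 >= m2
    nms[idx[keep, , drop = FALSE]] <- TRUE
  }

  strong <- nms & (mag >= high_frac * mmax)
  weak <- nms & (mag >= low_frac * mmax)
  # grow strong edges through weak pixels (8-connectivity) to a fixpoint
  edges <- strong
  repeat {
    grown <- edges
    sh <- function(m, dy, dx) {
      out <- matrix(FALSE, ny, nx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      out[ys, xs] <- m[ys - dy, xs - dx]
      out
    }
    nb <- sh(edges, 1, 0) | sh(edges, -1, 0) | sh(edges, 0, 1) | sh(edges, 0, -1) |
          sh(edges, 1, 1) | sh(edges, 1, -1) | sh(edges, -1, 1) | sh(edges, -1, -1)
    grown <- edges | (weak & nb)
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

# Binary dilation with a w x w all-ones structuring element, giving straight
# strokes an exact width of w pixels (w may be even).
dilate_square <- function(mask, w) {
  if (w <= 1) return(mask)
  conv_same(mask * 1, matrix(1, w, w)) > 0.5
}

#' Contour pattern from a noise field
#'
#' Extracts Canny edges from a Perlin noise field and dilates them to the
#' requested stroke width, producing the binary target pattern whose far-field
#' intensity the phase mask is designed to realize.
#'
#' @param field a `noise_field` (or a bare numeric matrix, in which case
#'   `pixel_pitch` must be supplied).
#' @param low_frac,high_frac Canny hysteresis fractions of the maximum
#'   gradient magnitude.
#' @param pattern_width stroke width in micrometres (design value 6).
#' @param sigma Canny Gaussian smoothing width in pixels.
#' @param pixel_pitch pixel pitch in micrometres, taken from `field` when it
#'   is a `noise_field`.
#' @return object of class `contour_pattern`: `mask` (logical matrix),
#'   `pixel_pitch`, `pattern_width`.
#' @export
contour_from_noise <- function(field, low_frac = 0.1, high_frac = 0.3,
                               pattern_width = 6, sigma = 1,
                               pixel_pitch = NULL) {
  if (inherits(field, "noise_field")) {
    pixel_pitch <- field$pixel_pitch
    img <- field$values
  } else {
    img <- field
    if (is.null(pixel_pitch)) stop("`pixel_pitch` required", call. = FALSE)
  }
  if (max(img) - min(img) == 0) {
    warning("constant field: contour pattern is empty")
    edges <- matrix(FALSE, nrow(img), ncol(img))
  } else {
    edges <- canny_edges(img, low_frac, high_frac, sigma)
  }
  w <- max(1L, as.integer(round(pattern_width / pixel_pitch)))
  structure(list(mask = dilate_square(edges, w), pixel_pitch = pixel_pitch,
                 pattern_width = pattern_width),
            class = "contour_pattern")
}

#' @export
print.contour_pattern <- function(x, ...) {
  cat(sprintf("<contour_pattern> %d x %d px, pitch %g um, stroke %g um, %d edge px\n",
              nrow(x$mask), ncol(x$mask), x$pixel_pitch, x$pattern_width,
              sum(x$mask)))
  invisible(x)
}

#' Angular-spectrum propagation
#'
#' Scalar free-space propagation of a sampled complex field by the angular
#' spectrum method.  Evanescent components (spatial frequencies beyond
#' \eqn{1/\lambda}) are zeroed.  A warning is issued when the transfer
#' function's phase is undersampled at the band edge (the propagated field
#' then wraps around the grid).
#'
#' @param field complex (or numeric) matrix.
#' @param distance propagation distance in millimetres (0 returns the input
#'   unchanged; negative propagates backwards).
#' @param wavelength wavelength in nanometres.
#' @param pixel_pitch sample spacing in micrometres.
#' @return complex matrix of the same size.
#' @export
propagate_angular_spectrum <- function(field, distance, wavelength, pixel_pitch) {
  stopifnot_positive(wavelength, "wavelength")
  stopifnot_positive(pixel_pitch, "pixel_pitch")
  if (distance == 0) return(field)
  z <- distance * 1e3          # um
  lam <- wavelength * 1e-3     # um
  fy <- fft_freq(nrow(field), pixel_pitch)
  fx <- fft_freq(ncol(field), pixel_pitch)
  F2 <- outer(fy^2, fx^2, "+")
  arg <- 1 / lam^2 - F2
  prop <- arg > 0
  # sampling check: phase increment between adjacent frequency samples at
  # the band edge must stay below pi
  fmax <- min(1 / (2 * pixel_pitch), 1 / lam)
  df <- max(1 / (nrow(field) * pixel_pitch), 1 / (ncol(field) * pixel_pitch))
  denom <- sqrt(max(1 / lam^2 - fmax^2, 0))
  if (denom == 0 || 2 * pi * abs(z) * fmax / denom * df > pi)
    warning("angular-spectrum kernel undersampled at this distance/pitch; ",
            "expect wrap-around artifacts")
  H <- matrix(0 + 0i, nrow(field), ncol(field))
  H[prop] <- exp(2i * pi * z * sqrt(arg[prop]))
  ifft2(fft2(field) * H)
}

# normalized cross-correlation between two images (Pearson over pixels)
ncc <- function(a, b) {
  a <- as.vector(a) - mean(a); b <- as.vector(b) - mean(b)
  s <- sqrt(sum(a^2) * sum(b^2))
  if (s == 0) return(0)
  sum(a * b) / s
}

#' Phase mask object
#'
#' Quantized height map of a refractive phase mask.  Heights are in
#' nanometres and must be integer multiples of `height_step` within
#' `[0, max_height]` (the fabrication process writes discrete levels).
#'
#' @param heights numeric matrix of heights in nm.
#' @param pixel_pitch fabrication pixel size in micrometres.
#' @param height_step fabrication height step in nm.
#' @param max_height maximum height in nm.
#' @param design_wavelength design wavelength in nm.
#' @param mask_to_sensor_distance mask-to-sensor distance in mm.
#' @param delta_n refractive-index contrast of the resist against air.
#' @param ... further metadata stored on the object (e.g. fidelity).
#' @return object of class `phase_mask`.
#' @export
phase_mask <- function(heights, pixel_pitch = 1, height_step = 200,
                       max_height = 1000, design_wavelength = 530,
                       mask_to_sensor_distance = 3.5, delta_n = 0.55, ...) {
  q <- heights / height_step
  if (max(abs(q - round(q))) > 1e-9)
    stop("heights must be integer multiples of height_step", call. = FALSE)
  if (min(heights) < -1e-9 || max(heights) > max_height + 1e-9)
    stop("heights must lie in [0, max_height]", call. = FALSE)
  structure(list(heights = heights, pixel_pitch = pixel_pitch,
                 height_step = height_step, max_height = max_height,
                 design_wavelength = design_wavelength,
                 mask_to_sensor_distance = mask_to_sensor_distance,
                 delta_n = delta_n, ...),
            class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf(paste0("<phase_mask> %d x %d px, pitch %g um, %d levels of %g nm, ",
                     "lambda %g nm, z %g mm\n"),
              nrow(x$heights), ncol(x$heights), x$pixel_pitch,
              length(unique(as.vector(x$heights))), x$height_step,
              x$design_wavelength, x$mask_to_sensor_distance))
  if (!is.null(x$fidelity))
    cat(sprintf("  design fidelity (NCC) %.4f%s\n", x$fidelity,
                if (isFALSE(x$converged)) " [below fidelity floor]" else ""))
  invisible(x)
}

# Phase delay (radians, in [0, 2 pi * delta_n * max_h / lambda)) of a mask at
# a given wavelength.
mask_phase <- function(mask, wavelength = mask$design_wavelength) {
  2 * pi * mask$delta_n * mask$heights / wavelength
}

#' Design a phase mask by iterative phase retrieval
#'
#' Error-reduction (Gerchberg-Saxton type) phase retrieval between the mask
#' plane (unit amplitude, free phase) and the sensor plane (amplitude clamped
#' to the square root of the target pattern), using angular-spectrum
#' propagation.  The retrieved phase is converted to a resist height via
#' \eqn{h = \phi \lambda / (2 \pi \Delta n)}, quantized to the fabrication
#' step and clipped to the maximum height.
#'
#' @param target a `contour_pattern` (nonempty) or binary matrix.
#' @param distance mask-to-sensor distance in mm.
#' @param wavelength design wavelength in nm.
#' @param n_iter number of retrieval iterations (>= 1).
#' @param seed seed for the random initial phase.
#' @param height_step,max_height fabrication quantization in nm.
#' @param delta_n refractive-index contrast (resist vs air).
#' @param pixel_pitch fabrication pixel pitch in micrometres (from `target`
#'   when it is a `contour_pattern`).
#' @param fidelity_floor normalized cross-correlation below which the design
#'   is flagged `converged = FALSE` (never an error).
#' @return a `phase_mask` carrying `fidelity` (NCC of the quantized mask's
#'   propagated intensity against the target), `fidelity_trace` (per
#'   iteration, unquantized), `phase` (unquantized retrieved phase) and
#'   `converged`.
#' @export
design_phase_mask <- function(target, distance = 3.5, wavelength = 530,
                              n_iter = 50, seed = 1L, height_step = 200,
                              max_height = 1000, delta_n = 0.55,
                              pixel_pitch = NULL, fidelity_floor = 0.3) {
  if (inherits(target, "contour_pattern")) {
    pixel_pitch <- target$pixel_pitch
    tgt <- target$mask * 1
  } else {
    tgt <- target * 1
    if (is.null(pixel_pitch)) stop("`pixel_pitch` required", call. = FALSE)
  }
  if (sum(tgt) == 0) stop("target pattern is empty", call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)

  amp <- sqrt(tgt)
  u_mask <- with_seed(seed, {
    exp(1i * matrix(stats::runif(length(tgt), 0, 2 * pi), nrow(tgt), ncol(tgt)))
  })
  fid <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    u_s <- propagate_angular_spectrum(u_mask, distance, wavelength, pixel_pitch)
    fid[it] <- ncc(Mod(u_s)^2, tgt)
    u_s <- amp * exp(1i * Arg(u_s))
    u_m <- propagate_angular_spectrum(u_s, -distance, wavelength, pixel_pitch)
    u_mask <- exp(1i * Arg(u_m))
  }
  phi <- Arg(u_mask) %% (2 * pi)
  h_cont <- phi * wavelength / (2 * pi * delta_n)    # nm
  h <- pmin(pmax(round(h_cont / height_step) * height_step, 0), max_height)

  uq <- exp(1i * 2 * pi * delta_n * h / wavelength)
  iq <- Mod(propagate_angular_spectrum(uq, distance, wavelength, pixel_pitch))^2
  fidelity <- ncc(iq, tgt)

  phase_mask(h, pixel_pitch = pixel_pitch, height_step = height_step,
             max_height = max_height, design_wavelength = wavelength,
             mask_to_sensor_distance = distance, delta_n = delta_n,
             fidelity = fidelity, fidelity_trace = fid, phase = phi,
             converged = fidelity >= fidelity_floor)
}
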