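# Image formation: incoherent PSF simulation from a phase mask, the
# shift-invariant and laterally varying (grid-interpolated) forward
# operators, and the sensor noise model.

#' Calibrated/simulated PSF grid
#'
#' Container for PSFs indexed by depth and lateral grid position: the data
#' behind the spatially varying forward operator.  Each PSF is normalized to
#' unit sum.  Grid node positions are given in scene pixel coordinates so
#' the interpolation windows are defined without unit juggling; the physical
#' grid (mm) metadata travels alongside.
#'
#' @param psfs 5-D array `(depth, grid_row, grid_col, y, x)` of nonnegative
#'   PSF images; a 4-D array is interpreted as a single depth, a matrix as a
#'   single PSF on a 1 x 1 grid.
#' @param depths strictly increasing depths in mm.
#' @param grid_rows,grid_cols grid node positions in scene pixel coordinates
#'   (must be increasing and span the scene for the operator to apply).
#' @param pixel_pitch sensor/PSF pixel pitch in micrometres.
#' @param grid_spacing_mm lateral spacing of the calibration grid in mm
#'   (metadata; the in-vivo calibration uses a 9 x 9 grid at 1 mm spacing).
#' @param normalize normalize each PSF to unit sum (default TRUE).
#' @return object of class `psf_grid`.
#' @export
psf_grid <- function(psfs, depths = 3.0, grid_rows = 1, grid_cols = 1,
                     pixel_pitch = 2.4, grid_spacing_mm = 1, normalize = TRUE) {
  if (is.matrix(psfs)) dim(psfs) <- c(1, 1, 1, nrow(psfs), ncol(psfs))
  if (length(dim(psfs)) == 4) dim(psfs) <- c(1, dim(psfs))
  if (length(dim(psfs)) != 5) stop("`psfs` must be a 5-D array", call. = FALSE)
  if (dim(psfs)[1] != length(depths)) stop("depths do not match psfs", call. = FALSE)
  if (dim(psfs)[2] != length(grid_rows) || dim(psfs)[3] != length(grid_cols))
    stop("grid node positions do not match psfs", call. = FALSE)
  if (length(depths) > 1 && any(diff(depths) <= 0))
    stop("`depths` must be strictly increasing", call. = FALSE)
  if (min(psfs) < 0) stop("PSFs must be nonnegative", call. = FALSE)
  if (normalize) {
    for (d in seq_len(dim(psfs)[1])) for (r in seq_len(dim(psfs)[2]))
      for (cc in seq_len(dim(psfs)[3])) {
        s <- sum(psfs[d, r, cc, , ])
        if (s <= 0) stop("PSF with zero energy", call. = FALSE)
        psfs[d, r, cc, , ] <- psfs[d, r, cc, , ] / s
      }
  }
  structure(list(psfs = psfs, depths = depths, grid_rows = grid_rows,
                 grid_cols = grid_cols, pixel_pitch = pixel_pitch,
                 grid_spacing_mm = grid_spacing_mm),
            class = "psf_grid")
}

#' @export
print.psf_grid <- function(x, ...) {
  d <- dim(x$psfs)
  cat(sprintf("<psf_grid> %d depth(s) x %d x %d grid, PSFs %d x %d px (pitch %g um)\n",
              d[1], d[2], d[3], d[4], d[5], x$pixel_pitch))
  cat(sprintf("  depths [mm]: %s\n", paste(format(x$depths), collapse = ", ")))
  invisible(x)
}

# PSF plane at a requested depth: exact match, or linear interpolation
# between the two bracketing calibrated depths.
psf_plane <- function(grid, depth, tol = 1e-9) {
  dd <- grid$depths
  j <- which(abs(dd - depth) < tol)
  nr <- length(grid$grid_rows); nc <- length(grid$grid_cols)
  out <- array(0, dim = dim(grid$psfs)[2:5])
  if (length(j) == 1) {
    out[] <- grid$psfs[j, , , , , drop = FALSE]
    return(out)
  }
  if (depth < min(dd) || depth > max(dd))
    stop(sprintf("depth %g mm outside calibrated range [%g, %g]",
                 depth, min(dd), max(dd)), call. = FALSE)
  j1 <- max(which(dd <= depth)); j2 <- j1 + 1L
  w <- (depth - dd[j1]) / (dd[j2] - dd[j1])
  out[] <- (1 - w) * grid$psfs[j1, , , , , drop = FALSE] +
           w * grid$psfs[j2, , , , , drop = FALSE]
  out
}

#' Simulate the incoherent PSF of a phase mask
#'
#' Propagates a spherical wave from a point source at the given depth and
#' lateral offset to the mask plane, applies the mask's phase profile, and
#' propagates to the sensor by the mask-to-sensor distance; the intensity
#' is normalized to unit sum.  This is the simulated counterpart of the
#' pinhole calibration captures.
#'
#' @param mask a `phase_mask`.
#' @param depth source distance in front of the mask, mm (> 0).
#' @param wavelength wavelength in nm (defaults to the design wavelength).
#' @param source_offset length-2 lateral source offset `(y, x)` in mm.
#' @param crop optional output size in pixels (center crop); default full grid.
#' @return nonnegative matrix summing to 1.
#' @export
simulate_psf <- function(mask, depth, wavelength = mask$design_wavelength,
                         source_offset = c(0, 0), crop = NULL) {
  stopifnot_positive(depth, "depth")
  ny <- nrow(mask$heights); nx <- ncol(mask$heights)
  pitch <- mask$pixel_pitch                       # um
  lam <- wavelength * 1e-3                        # um
  z1 <- depth * 1e3                               # um
  y <- (seq_len(ny) - (ny + 1) / 2) * pitch - source_offset[1] * 1e3
  x <- (seq_len(nx) - (nx + 1) / 2) * pitch - source_offset[2] * 1e3
  r <- sqrt(outer(y^2, x^2, "+") + z1^2)
  u <- exp(2i * pi * r / lam) / r                 # spherical wave at mask
  u <- u * exp(1i * mask_phase(mask, wavelength))
  u <- propagate_angular_spectrum(u, mask$mask_to_sensor_distance,
                                  wavelength, pitch)
  psf <- Mod(u)^2
  if (!is.null(crop)) {
    cy <- floor((ny - crop[1]) / 2); cx <- floor((nx - crop[2]) / 2)
    psf <- psf[(cy + 1):(cy + crop[1]), (cx + 1):(cx + crop[2])]
  }
  psf / sum(psf)
}

#' Shift-invariant forward model
#'
#' Linear (zero-padded) convolution of the scene with a single PSF, cropped
#' to the sensor size with the package-wide centering convention: a delta
#' scene returns the PSF centered at the delta's position.
#'
#' @param scene nonnegative matrix (object plane).
#' @param psf nonnegative matrix.
#' @return matrix of the scene's size.
#' @export
forward_shift_invariant <- function(scene, psf) {
  if (min(scene) < 0 || min(psf) < 0)
    stop("scene and psf must be nonnegative", call. = FALSE)
  conv_same(scene, psf)
}

# Bilinear interpolation windows over grid node positions (pixel coords).
# Returns an (n_nodes x n) matrix of 1-D hat weights; rows sum to 1 for
# every coordinate inside [min(nodes), max(nodes)].
hat_weights <- function(nodes, n) {
  m <- length(nodes)
  W <- matrix(0, m, n)
  xs <- seq_len(n)
  if (m == 1) { W[1, ] <- 1; return(W) }
  if (min(xs) < nodes[1] - 1e-9 || max(xs) > nodes[m] + 1e-9)
    stop("scene extends outside the calibrated grid hull", call. = FALSE)
  for (k in seq_len(m - 1)) {
    sel <- xs >= nodes[k] & xs <= nodes[k + 1]
    t <- (xs[sel] - nodes[k]) / (nodes[k + 1] - nodes[k])
    W[k, sel] <- pmax(W[k, sel], 1 - t)
    W[k + 1, sel] <- pmax(W[k + 1, sel], t)
  }
  W
}

# Precompute the pieces of the shift-variant operator at one depth:
# interpolation windows and padded-kernel OTFs.
shift_variant_plan <- function(grid, depth, dim_scene) {
  pk <- psf_plane(grid, depth)
  nr <- dim(pk)[1]; nc <- dim(pk)[2]
  plan <- conv_plan(dim_scene, dim(pk)[3:4])
  Wr <- hat_weights(grid$grid_rows, dim_scene[1])
  Wc <- hat_weights(grid$grid_cols, dim_scene[2])
  wins <- vector("list", nr * nc)
  otfs <- vector("list", nr * nc)
  k <- 1L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    wins[[k]] <- outer(Wr[r, ], Wc[cc, ])
    otfs[[k]] <- psf_otf(matrix(pk[r, cc, , ], dim(pk)[3], dim(pk)[4]), plan)
    k <- k + 1L
  }
  list(plan = plan, wins = wins, otfs = otfs)
}

# Split the FFT of (a + i b), a and b real, into the two spectra using
# conjugate symmetry (two real transforms for the price of one).
unpack_pair <- function(F12) {
  rev_idx <- function(n) c(1L, n:2L)
  Frev <- Conj(F12[rev_idx(nrow(F12)), rev_idx(ncol(F12))])
  list((F12 + Frev) / 2, (F12 - Frev) / (2i))
}

apply_forward_sv <- function(scene, svp) {
  p <- svp$plan
  nk <- length(svp$wins)
  acc <- matrix(0 + 0i, p$py, p$px)
  k <- 1L
  while (k <= nk) {
    if (k + 1L <= nk) {  # pack two real window products into one FFT
      F12 <- fft2(pad_at(svp$wins[[k]] * scene + 1i * (svp$wins[[k + 1L]] * scene),
                         p$py, p$px))
      Fs <- unpack_pair(F12)
      acc <- acc + Fs[[1]] * svp$otfs[[k]] + Fs[[2]] * svp$otfs[[k + 1L]]
      k <- k + 2L
    } else {
      acc <- acc + fft2(pad_at(svp$wins[[k]] * scene, p$py, p$px)) * svp$otfs[[k]]
      k <- k + 1L
    }
  }
  full <- ifft2(acc)
  Re(full[p$cy:(p$cy + p$ny - 1L), p$cx:(p$cx + p$nx - 1L)])
}

apply_adjoint_sv <- function(meas, svp) {
  p <- svp$plan
  nk <- length(svp$wins)
  Fm <- fft2(pad_at(meas, p$py, p$px, p$cy, p$cx))
  out <- matrix(0, p$ny, p$nx)
  k <- 1L
  while (k <= nk) {
    if (k + 1L <= nk) {  # both correlation spectra are conjugate-symmetric
      full <- ifft2(Fm * Conj(svp$otfs[[k]]) + 1i * (Fm * Conj(svp$otfs[[k + 1L]])))
      win <- full[1:p$ny, 1:p$nx]
      out <- out + svp$wins[[k]] * Re(win) + svp$wins[[k + 1L]] * Im(win)
      k <- k + 2L
    } else {
      full <- ifft2(Fm * Conj(svp$otfs[[k]]))
      out <- out + svp$wins[[k]] * Re(full[1:p$ny, 1:p$nx])
      k <- k + 1L
    }
  }
  out
}

#' Spatially varying forward model
#'
#' Applies the grid-interpolated forward operator
#' \eqn{\Phi i = \sum_k (w_k \odot i) * p_k}, where \eqn{p_k} are the PSFs
#' calibrated on a lateral grid at the requested depth and \eqn{w_k} are
#' bilinear interpolation windows forming a partition of unity over the
#' field of view.  Exact at grid nodes, continuous in between.
#'
#' @param scene nonnegative matrix, its extent within the calibrated hull.
#' @param grid a `psf_grid`.
#' @param depth depth in mm (calibrated or interpolable).
#' @return matrix of the scene's size.
#' @export
forward_shift_variant <- function(scene, grid, depth = grid$depths[1]) {
  if (min(scene) < 0) stop("scene must be nonnegative", call. = FALSE)
  svp <- shift_variant_plan(grid, depth, dim(scene))
  apply_forward_sv(scene, svp)
}

#' Sensor noise model
#'
#' Shot noise as a scaled Poisson process plus Gaussian read noise, then
#' clipping and quantization to the sensor bit depth:
#' `Poisson(photon_scale * m) / photon_scale + N(0, read_sigma)`.
#'
#' @param measurement matrix or 3-D array `(time, y, x)` of noiseless sensor
#'   values (arbitrary nonnegative units).
#' @param photon_scale expected photons (counts) per measurement unit;
#'   larger means less shot noise.  `Inf` disables shot noise.
#' @param read_sigma Gaussian read-noise SD in measurement units.
#' @param seed integer seed (same seed, same noise).
#' @param bit_depth sensor bit depth; quantization maps `full_scale` to the
#'   top code.  `NULL` disables clipping/quantization.
#' @param full_scale measurement value mapped to the maximum code.
#' @return noisy array of the input's shape (quantized to `2^bit_depth`
#'   levels when `bit_depth` is set).
#' @export
add_sensor_noise <- function(measurement, photon_scale = 1000, read_sigma = 0.5,
                             seed = 1L, bit_depth = 8L,
                             full_scale = max(measurement)) {
  if (!is.infinite(photon_scale)) stopifnot_positive(photon_scale, "photon_scale")
  m <- pmax(measurement, 0)
  out <- with_seed(seed, {
    v <- if (is.infinite(photon_scale)) m
         else array(stats::rpois(length(m), as.vector(m) * photon_scale),
                    dim = dim(m)) / photon_scale
    if (read_sigma > 0)
      v <- v + array(stats::rnorm(length(m), 0, read_sigma), dim = dim(m))
    v
  })
  if (!is.null(bit_depth)) {
    qmax <- 2^bit_depth - 1
    if (full_scale <= 0) full_scale <- 1
    out <- round(pmin(pmax(out / full_scale, 0), 1) * qmax) / qmax * full_scale
  }
  out
}
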