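# Internal numerical utilities shared across modules: FFT-based linear
# convolution with a fixed padding/cropping convention, DFT frequency grids,
# orthonormal DCT-II matrices, and scoped RNG seeding.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# DFT sample frequencies (cycles per unit), matching the unnormalized fft
# ordering: 0, 1/(n d), ..., then negative frequencies.
fft_freq <- function(n, d = 1) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k / (n * d)
}

# Smallest 5-smooth integer >= n (fast mixed-radix FFT sizes).
good_fft_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Kernel "center" pixel used by the same-crop convention: for an odd kernel
# this is the middle sample, for an even one the sample just above the middle.
kernel_center <- function(k) (k %/% 2) + 1L

# Zero-pad a matrix to py x px, placing it at rows/cols starting at (r0, c0).
pad_at <- function(x, py, px, r0 = 1L, c0 = 1L) {
  out <- matrix(0, py, px)
  out[r0:(r0 + nrow(x) - 1L), c0:(c0 + ncol(x) - 1L)] <- x
  out
}

# Shared plan for linear convolution of an ny x nx scene with a ky x kx
# kernel: padded grid size and the offset of the "same" crop.  The identical
# plan is used by the forward operators, their adjoints and the Wiener
# inverse so that the round trip is self-consistent.
conv_plan <- function(dim_scene, dim_psf) {
  py <- good_fft_size(dim_scene[1] + dim_psf[1] - 1L)
  px <- good_fft_size(dim_scene[2] + dim_psf[2] - 1L)
  list(py = py, px = px,
       cy = kernel_center(dim_psf[1]), cx = kernel_center(dim_psf[2]),
       ny = dim_scene[1], nx = dim_scene[2])
}

# F(psf) on the padded grid (psf embedded at the top-left corner).
psf_otf <- function(psf, plan) {
  fft2(pad_at(psf, plan$py, plan$px))
}

# Linear convolution of scene with psf, cropped so that a delta at (r, c)
# returns the psf centered at (r, c).  `otf` may be precomputed.
conv_same <- function(scene, psf = NULL, plan = NULL, otf = NULL) {
  if (is.null(plan)) plan <- conv_plan(dim(scene), dim(psf))
  if (is.null(otf)) otf <- psf_otf(psf, plan)
  full <- ifft2(fft2(pad_at(scene, plan$py, plan$px)) * otf)
  Re(full[plan$cy:(plan$cy + plan$ny - 1L), plan$cx:(plan$cx + plan$nx - 1L)])
}

# Exact adjoint of conv_same under the same plan: embed the measurement at
# the crop offset, correlate with the kernel, read back the scene window.
corr_same_adjoint <- function(meas, plan, otf) {
  full <- ifft2(fft2(pad_at(meas, plan$py, plan$px, plan$cy, plan$cx)) * Conj(otf))
  Re(full[1:plan$ny, 1:plan$nx])
}

# Orthonormal DCT-II matrix of order n: (C %*% x) is the 1D DCT of x.
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(2 * k + 1, k) / (2 * n))
  C[, 1] <- C[, 1] / sqrt(2)
  t(C)
}

dct2 <- function(x, Cr = dct_matrix(nrow(x)), Cc = dct_matrix(ncol(x))) {
  Cr %*% x %*% t(Cc)
}

idct2 <- function(x, Cr = dct_matrix(nrow(x)), Cc = dct_matrix(ncol(x))) {
  t(Cr) %*% x %*% Cc
}

stopifnot_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
}
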