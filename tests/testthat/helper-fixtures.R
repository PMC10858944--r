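# Shared fixtures and independent oracle implementations.  Oracles are
# deliberately written as direct loops / explicit matrices, independent of
# the package's FFT code paths.

rel_err <- function(est, truth) sqrt(sum((est - truth)^2) / sum(truth^2))

# well-conditioned random test PSF: dominant centre plus a scattered tail
# (keeps the transfer function bounded away from zero)
conditioned_psf <- function(k = 3, peak = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- matrix(runif(k * k), k, k) * 0.3
  ctr <- (k + 1) %/% 2
  p[ctr, ctr] <- p[ctr, ctr] + peak
  p / sum(p)
}

# 2x2 grid of conditioned PSFs spanning an n x n scene
conditioned_grid <- function(n, k = 3, peak = 5, seed = 1) {
  set.seed(seed)
  psfs <- array(0, c(1, 2, 2, k, k))
  for (r in 1:2) for (cc in 1:2) psfs[1, r, cc, , ] <- conditioned_psf(k, peak)
  psf_grid(psfs, grid_rows = c(1, n), grid_cols = c(1, n), normalize = FALSE)
}

# dense matrix representation of a forward operator, built column by column
# by pushing unit impulses through the supplied function
dense_operator <- function(fwd, n) {
  Phi <- matrix(0, n * n, n * n)
  for (k in seq_len(n * n)) {
    e <- matrix(0, n, n)
    e[k] <- 1
    Phi[, k] <- as.vector(fwd(e))
  }
  Phi
}

# explicit (slow) DFT matrix, independent of stats::fft
dft_matrix <- function(N) exp(-2i * pi * outer(0:(N - 1), 0:(N - 1)) / N)

# direct quadruple-sum orthonormal DCT-II and its inverse
dct2_direct <- function(x) {
  N1 <- nrow(x); N2 <- ncol(x)
  out <- matrix(0, N1, N2)
  for (u in 0:(N1 - 1)) for (v in 0:(N2 - 1)) {
    s <- 0
    for (a in 0:(N1 - 1)) for (b in 0:(N2 - 1))
      s <- s + x[a + 1, b + 1] *
        cos(pi * (2 * a + 1) * u / (2 * N1)) *
        cos(pi * (2 * b + 1) * v / (2 * N2))
    cu <- if (u == 0) sqrt(1 / N1) else sqrt(2 / N1)
    cv <- if (v == 0) sqrt(1 / N2) else sqrt(2 / N2)
    out[u + 1, v + 1] <- cu * cv * s
  }
  out
}

idct2_direct <- function(X) {
  N1 <- nrow(X); N2 <- ncol(X)
  out <- matrix(0, N1, N2)
  for (a in 0:(N1 - 1)) for (b in 0:(N2 - 1)) {
    s <- 0
    for (u in 0:(N1 - 1)) for (v in 0:(N2 - 1)) {
      cu <- if (u == 0) sqrt(1 / N1) else sqrt(2 / N1)
      cv <- if (v == 0) sqrt(1 / N2) else sqrt(2 / N2)
      s <- s + cu * cv * X[u + 1, v + 1] *
        cos(pi * (2 * a + 1) * u / (2 * N1)) *
        cos(pi * (2 * b + 1) * v / (2 * N2))
    }
    out[a + 1, b + 1] <- s
  }
  out
}

# independent loop-based Canny reference following the same algorithm
# definition (Gaussian smoothing, Sobel, 4-sector NMS, hysteresis)
canny_reference <- function(img, low_frac = 0.1, high_frac = 0.3, sigma = 1) {
  ny <- nrow(img); nx <- ncol(img)
  # Gaussian smoothing with reflective boundaries, done with explicit loops
  r <- max(1, ceiling(3 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  refl <- function(i, n) { i <- ifelse(i < 1, 1 - i + 1, i); ifelse(i > n, 2 * n - i + 1, i) }
  sm <- matrix(0, ny, nx)
  tmp <- matrix(0, ny, nx)
  for (y in 1:ny) for (x in 1:nx) {
    s <- 0
    for (d in -r:r) s <- s + k1[d + r + 1] * img[refl(y + d, ny), x]
    tmp[y, x] <- s
  }
  for (y in 1:ny) for (x in 1:nx) {
    s <- 0
    for (d in -r:r) s <- s + k1[d + r + 1] * tmp[y, refl(x + d, nx)]
    sm[y, x] <- s
  }
  gy <- matrix(0, ny, nx); gx <- matrix(0, ny, nx)
  for (y in 2:(ny - 1)) for (x in 2:(nx - 1)) {
    gy[y, x] <- (sm[y + 1, x - 1] + 2 * sm[y + 1, x] + sm[y + 1, x + 1]) -
                (sm[y - 1, x - 1] + 2 * sm[y - 1, x] + sm[y - 1, x + 1])
    gx[y, x] <- (sm[y - 1, x + 1] + 2 * sm[y, x + 1] + sm[y + 1, x + 1]) -
                (sm[y - 1, x - 1] + 2 * sm[y, x - 1] + sm[y + 1, x - 1])
  }
  mag <- sqrt(gy^2 + gx^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, ny, nx))
  nms <- matrix(FALSE, ny, nx)
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (y in 2:(ny - 1)) for (x in 2:(nx - 1)) {
    if (mag[y, x] == 0) next
    s <- round(atan2(gy[y, x], gx[y, x]) / (pi / 4)) %% 4
    d <- offs[[s + 1]]
    if (mag[y, x] >= mag[y + d[1], x + d[2]] && mag[y, x] >= mag[y - d[1], x - d[2]])
      nms[y, x] <- TRUE
  }
  strong <- nms & (mag >= high_frac * mmax)
  weak <- nms & (mag >= low_frac * mmax)
  edges <- strong
  repeat {
    changed <- FALSE
    for (y in 2:(ny - 1)) for (x in 2:(nx - 1)) {
      if (weak[y, x] && !edges[y, x] &&
          any(edges[(y - 1):(y + 1), (x - 1):(x + 1)])) {
        edges[y, x] <- TRUE; changed <- TRUE
      }
    }
    if (!changed) break
  }
  edges
}

# simple 8-connected component labelling by flood fill (test-side oracle
# for bar-geometry measurements)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      y <- (k - 1) %% nrow(mask) + 1; x <- (k - 1) %/% nrow(mask) + 1
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= nrow(mask) && xx >= 1 && xx <= ncol(mask)) {
          kk <- (xx - 1) * nrow(mask) + yy
          if (mask[kk] && lab[kk] == 0L) { lab[kk] <- cur; queue <- c(queue, kk) }
        }
      }
    }
  }
  lab
}
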