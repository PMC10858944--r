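test_that("shift-invariant forward model: impulse response, linearity, direct-convolution oracle", {
  set.seed(2)
  scene <- matrix(0, 32, 32); scene[17, 13] <- 1
  psf <- matrix(runif(49), 7, 7)
  b <- forward_shift_invariant(scene, psf)
  expect_lt(max(abs(b[14:20, 10:16] - psf)), 1e-12)

  s1 <- matrix(runif(256), 16, 16); s2 <- matrix(runif(256), 16, 16)
  expect_lt(max(abs(forward_shift_invariant(2.5 * s1 + 0.7 * s2, psf) -
                    (2.5 * forward_shift_invariant(s1, psf) +
                     0.7 * forward_shift_invariant(s2, psf)))), 1e-10)

  # 16x16 scene / 7x7 psf against a nested-loop spatial convolution
  direct <- matrix(0, 16, 16)
  cy <- 4; cx <- 4
  for (r in 1:16) for (cc in 1:16) {
    acc <- 0
    for (a in 1:16) for (bb in 1:16) {
      dr <- r - a + cy; dc <- cc - bb + cx
      if (dr >= 1 && dr <= 7 && dc >= 1 && dc <= 7)
        acc <- acc + s1[a, bb] * psf[dr, dc]
    }
    direct[r, cc] <- acc
  }
  expect_lt(max(abs(forward_shift_invariant(s1, psf) - direct)), 1e-9)

  expect_error(forward_shift_invariant(-s1, psf), "nonnegative")
})

test_that("shift-variant operator equals the explicit dense matrix and degenerates correctly", {
  set.seed(3)
  n <- 12
  psfs <- array(runif(2 * 2 * 9), c(1, 2, 2, 3, 3))
  g <- psf_grid(psfs, grid_rows = c(1, n), grid_cols = c(1, n))
  scene <- matrix(runif(n * n), n, n)

  Phi <- dense_operator(function(e) forward_shift_variant(e, g), n)
  expect_lt(max(abs(as.vector(forward_shift_variant(scene, g)) -
                    Phi %*% as.vector(scene))), 1e-9)

  # zero scene -> zero measurement
  expect_identical(forward_shift_variant(matrix(0, n, n), g),
                   matrix(0, n, n))

  # all grid PSFs identical -> shift-invariant model
  p1 <- matrix(runif(9), 3, 3); p1 <- p1 / sum(p1)
  psfs2 <- array(0, c(1, 2, 2, 3, 3))
  for (r in 1:2) for (cc in 1:2) psfs2[1, r, cc, , ] <- p1
  g2 <- psf_grid(psfs2, grid_rows = c(1, n), grid_cols = c(1, n))
  expect_lt(max(abs(forward_shift_variant(scene, g2) -
                    forward_shift_invariant(scene, p1))), 1e-9)

  # scene outside the calibrated hull is refused
  g3 <- psf_grid(psfs, grid_rows = c(3, n - 3), grid_cols = c(1, n))
  expect_error(forward_shift_variant(scene, g3), "hull")
})

test_that("interpolation windows form a partition of unity and the operator is linear", {
  n <- 20
  set.seed(4)
  psfs <- array(runif(3 * 3 * 25), c(1, 3, 3, 5, 5))
  g <- psf_grid(psfs, grid_rows = c(1, 10, n), grid_cols = c(1, 8, n))
  svp <- contourscope:::shift_variant_plan(g, g$depths[1], c(n, n))
  W <- Reduce(`+`, svp$wins)
  expect_lt(max(abs(W - 1)), 1e-12)

  # random superposition linearity
  for (rep in 1:3) {
    a <- runif(2, -2, 2)
    s1 <- matrix(runif(n * n), n); s2 <- matrix(runif(n * n), n)
    lhs <- contourscope:::apply_forward_sv(a[1] * s1 + a[2] * s2, svp)
    rhs <- a[1] * contourscope:::apply_forward_sv(s1, svp) +
           a[2] * contourscope:::apply_forward_sv(s2, svp)
    expect_lt(max(abs(lhs - rhs)), 1e-10)
  }

  # energy bookkeeping: unit-sum PSFs, interior scene
  sc <- matrix(0, n, n); sc[8:13, 8:13] <- runif(36)
  expect_equal(sum(contourscope:::apply_forward_sv(sc, svp)), sum(sc),
               tolerance = 1e-6)

  # adjoint consistency (needed by FISTA)
  x <- matrix(runif(n * n), n); y <- matrix(runif(n * n), n)
  expect_equal(sum(contourscope:::apply_forward_sv(x, svp) * y),
               sum(x * contourscope:::apply_adjoint_sv(y, svp)),
               tolerance = 1e-10)
})

test_that("simulated PSFs shift with the source according to the system magnification", {
  f <- generate_perlin_noise(192, 2, 16, seed = 5)
  pat <- contour_from_noise(f, pattern_width = 6)
  mk <- suppressWarnings(design_phase_mask(pat, distance = 1, n_iter = 15,
                                           seed = 1, pixel_pitch = 2))
  z1 <- 2    # source depth, mm
  p0 <- suppressWarnings(simulate_psf(mk, depth = z1))
  # lateral source shift of delta: pattern shifts by -delta * z2 / z1
  # (similar triangles through the mask centre); oracle = re-simulation at
  # the shifted position, shift read from the cross-correlation peak
  for (delta_um in c(16, 40)) {
    p1 <- suppressWarnings(simulate_psf(mk, depth = z1,
                                        source_offset = c(0, delta_um * 1e-3)))
    cp <- contourscope:::fft2(p1) * Conj(contourscope:::fft2(p0))
    xc <- Re(contourscope:::ifft2(cp))
    pk <- which(xc == max(xc), arr.ind = TRUE)[1, ]
    dx <- pk[2] - 1; if (dx > ncol(p0) / 2) dx <- dx - ncol(p0)
    dy <- pk[1] - 1; if (dy > nrow(p0) / 2) dy <- dy - nrow(p0)
    sub <- contourscope:::upsampled_peak(cp, dy, dx, 20)
    expected_px <- -delta_um * (mk$mask_to_sensor_distance / z1) / mk$pixel_pitch
    expect_equal(sub[2], expected_px, tolerance = 0.1)
    expect_equal(sub[1], 0, tolerance = 0.1)
  }

  # zero-height mask: PSF equals the free-space diffraction blur of the
  # point source (reference built explicitly in the test)
  m0 <- phase_mask(matrix(0, 64, 64), mask_to_sensor_distance = 0.4)
  pfree <- suppressWarnings(simulate_psf(m0, depth = 3))
  yv <- seq_len(64) - 65 / 2
  r <- sqrt(outer(yv^2, yv^2, "+") + (3e3)^2)
  u <- exp(2i * pi * r / 0.53) / r
  uref <- suppressWarnings(propagate_angular_spectrum(u, 0.4, 530, 1))
  pref <- Mod(uref)^2; pref <- pref / sum(pref)
  expect_lt(max(abs(pfree - pref)), 1e-12)

  # calibration depth plan: 2.9 to 3.1 mm at 20 um intervals = 11 planes
  depths <- seq(2.9, 3.1, by = 0.02)
  expect_length(depths, 11)
  expect_error(simulate_psf(mk, depth = -1), "depth")
})

test_that("sensor noise model is seeded, exact in the noiseless limit, and variance-calibrated", {
  set.seed(6)
  m <- matrix(runif(64, 0.2, 0.8), 8, 8)
  n1 <- add_sensor_noise(m, photon_scale = 500, read_sigma = 0.01, seed = 9)
  n2 <- add_sensor_noise(m, photon_scale = 500, read_sigma = 0.01, seed = 9)
  expect_identical(n1, n2)

  # noiseless limit: read_sigma 0, photon_scale infinite -> quantized input
  q <- add_sensor_noise(m, photon_scale = Inf, read_sigma = 0, seed = 1,
                        bit_depth = 8, full_scale = 1)
  expect_lt(max(abs(q - m)), 1 / 255 / 2 + 1e-12)

  # Monte-Carlo variance oracle: var = m * scale / scale^2 + sigma^2
  ps <- 200; rs <- 0.03; val <- 0.5
  draws <- vapply(1:1000, function(s)
    add_sensor_noise(matrix(val, 1, 1), photon_scale = ps, read_sigma = rs,
                     seed = s, bit_depth = NULL)[1, 1], 0)
  v_theory <- val / ps + rs^2
  expect_equal(stats::var(draws), v_theory, tolerance = 0.05)
})
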