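test_that("Wiener solver: identity kernel, exact inversion limit, per-frequency oracle", {
  set.seed(1)
  b <- matrix(runif(64), 8, 8)
  expect_lt(max(abs(wiener_reconstruct(b, matrix(1, 1, 1), gamma = 0) - b)),
            1e-12)

  # noiseless interior-supported scene, PSF without spectral zeros
  scene <- matrix(0, 64, 64)
  scene[20:44, 20:44] <- matrix(runif(625), 25)
  p <- conditioned_psf(9, peak = 2, seed = 2)
  meas <- forward_shift_invariant(scene, p)
  ih <- wiener_reconstruct(meas, p, gamma = 1e-12)
  expect_lt(rel_err(ih, scene), 1e-6)

  # 8x8 per-frequency oracle with explicit DFT matrices
  b8 <- matrix(runif(64), 8, 8)
  p8 <- matrix(runif(64), 8, 8)
  plan <- contourscope:::conv_plan(c(8, 8), c(8, 8))
  Wy <- dft_matrix(plan$py); Wx <- dft_matrix(plan$px)
  Fp <- Wy %*% contourscope:::pad_at(p8, plan$py, plan$px) %*% Wx
  Fb <- Wy %*% contourscope:::pad_at(b8, plan$py, plan$px, plan$cy, plan$cx) %*% Wx
  Ih <- Conj(Fp) * Fb / (Mod(Fp)^2 + 0.1)
  oracle <- Re((Conj(Wy) %*% Ih %*% Conj(Wx)) / (plan$py * plan$px))[1:8, 1:8]
  expect_lt(max(abs(wiener_reconstruct(b8, p8, gamma = 0.1) - oracle)), 1e-9)

  expect_error(wiener_reconstruct(b8, matrix(0, 3, 3)), "nonzero")
  # gamma = 0 with spectral zeros (two-point PSF on an even padded grid)
  pz <- matrix(c(0.5, 0.5), 1, 2)
  expect_error(wiener_reconstruct(matrix(runif(121), 11, 11), pz, gamma = 0),
               "spectral zeros")
})

test_that("Wiener solution satisfies the Fourier-domain normal equations", {
  set.seed(2)
  b <- matrix(runif(256), 16, 16)
  p <- matrix(runif(25), 5, 5)
  gamma <- 0.05
  plan <- contourscope:::conv_plan(dim(b), dim(p))
  otf <- contourscope:::psf_otf(p, plan)
  B <- contourscope:::fft2(contourscope:::pad_at(b, plan$py, plan$px,
                                                 plan$cy, plan$cx))
  Ihat <- Conj(otf) * B / (Mod(otf)^2 + gamma)
  # (|P|^2 + gamma) I = conj(P) B, spot-checked at every frequency
  expect_lt(max(Mod((Mod(otf)^2 + gamma) * Ihat - Conj(otf) * B)), 1e-9)
  # and the solver returns exactly this solution
  ih <- wiener_reconstruct(b, p, gamma)
  expect_lt(max(abs(ih - Re(contourscope:::ifft2(Ihat))[1:16, 1:16])), 1e-12)
})

test_that("DCT background projection keeps exactly the low-frequency block", {
  set.seed(3)
  g <- matrix(rnorm(256), 16, 16)
  pg <- dct_background_project(g, 5)
  G <- dct2_direct(g)
  G[-(1:5), ] <- 0; G[, -(1:5)] <- 0
  expect_lt(max(abs(pg - idct2_direct(G))), 1e-10)
  expect_identical(sum(abs(dct2_direct(pg)) > 1e-9), 25L)

  # constant image is untouched (DC is inside the block); full band = identity
  expect_lt(max(abs(dct_background_project(matrix(3, 8, 8), 5) - 3)), 1e-12)
  expect_lt(max(abs(dct_background_project(g, 16) - g)), 1e-12)
  expect_error(dct_background_project(g, 17), "exceeds")
})

test_that("FISTA converges to the Tikhonov closed form when unconstrained", {
  set.seed(4)
  p <- conditioned_psf(3, peak = 3)
  grid <- psf_grid(array(p, c(1, 1, 1, 3, 3)), grid_rows = 8, grid_cols = 8,
                   normalize = FALSE)
  scene <- matrix(0, 16, 16); scene[5:12, 5:12] <- runif(64)
  b <- forward_shift_invariant(scene, p)
  gamma <- 1e-6
  est <- fista_reconstruct(b, grid,
                           recon_config(gamma = gamma, max_iter = 500, tol = 0,
                                        nonneg = FALSE, background = FALSE))
  # the quadratic objective ||Phi i - b||^2 + (gamma/2)||i||^2 matches the
  # Wiener denominator |P|^2 + gamma/2
  w <- wiener_reconstruct(b, p, gamma = gamma / 2)
  expect_lt(rel_err(est$image, w), 1e-4)
})

test_that("FISTA recovers a planted scene-plus-background decomposition", {
  set.seed(5)
  n <- 16
  grid <- conditioned_grid(n, seed = 5)
  svp <- contourscope:::shift_variant_plan(grid, grid$depths[1], c(n, n))
  istar <- matrix(0, n, n)
  istar[sample(n * n, 25)] <- runif(25, 0.5, 1)
  Cd <- contourscope:::dct_matrix(n)
  Gc <- matrix(0, n, n); Gc[1:3, 1:3] <- rnorm(9) * 0.2; Gc[1, 1] <- 1
  gstar <- t(Cd) %*% Gc %*% Cd
  b <- contourscope:::apply_forward_sv(istar, svp) + gstar

  est <- fista_reconstruct(b, grid,
                           recon_config(gamma = 1e-5, max_iter = 6000, tol = 0))
  # planted-solution recovery (the scattered support pins the split
  # between scene and low-frequency background)
  expect_lt(rel_err(est$image, istar), 1e-2)
  # objective trace is non-increasing (restarts enforced)
  expect_true(all(diff(est$objective_trace) <=
                  1e-10 * abs(est$objective_trace[-1]) + 1e-15))
  # background stays in the DCT subspace
  Gb <- contourscope:::dct2(est$background)
  expect_lt(max(abs(Gb[-(1:5), ])), 1e-9)
  expect_lt(max(abs(Gb[, -(1:5)])), 1e-9)
  expect_true(all(est$image >= 0))
})

test_that("FISTA objective at convergence matches a quadratic-programming oracle", {
  set.seed(5)
  n <- 12
  grid <- conditioned_grid(n, seed = 5)
  svp <- contourscope:::shift_variant_plan(grid, grid$depths[1], c(n, n))
  istar <- matrix(0, n, n)
  istar[sample(n * n, 20)] <- runif(20, 0.5, 1)
  Cd <- contourscope:::dct_matrix(n)
  Gc <- matrix(0, n, n); Gc[1:3, 1:3] <- rnorm(9) * 0.2; Gc[1, 1] <- 1
  gstar <- t(Cd) %*% Gc %*% Cd
  b <- contourscope:::apply_forward_sv(istar, svp) + gstar
  gamma <- 1e-5

  est <- fista_reconstruct(b, grid,
                           recon_config(gamma = gamma, max_iter = 6000, tol = 0))

  # QP oracle: eliminate g, solve the augmented NNLS with Lawson-Hanson
  Phi <- dense_operator(function(e) contourscope:::apply_forward_sv(e, svp), n)
  keep <- 5
  B <- matrix(0, n * n, keep * keep); cnt <- 1
  for (u in 1:keep) for (v in 1:keep) {
    E <- matrix(0, n, n); E[u, v] <- 1
    B[, cnt] <- as.vector(t(Cd) %*% E %*% Cd); cnt <- cnt + 1
  }
  P <- B %*% t(B)
  A <- (diag(n * n) - P) %*% Phi
  cvec <- as.vector((diag(n * n) - P) %*% as.vector(b))
  sol <- pracma::lsqnonneg(rbind(A, sqrt(gamma / 2) * diag(n * n)),
                           c(cvec, rep(0, n * n)))
  gopt <- P %*% (as.vector(b) - Phi %*% sol$x)
  f_opt <- sum((Phi %*% sol$x + gopt - as.vector(b))^2) +
           gamma / 2 * sum(sol$x^2)
  f_fista <- tail(est$objective_trace, 1)
  expect_lt(abs(f_fista - f_opt), 1e-6)
})

test_that("reconstruction error decreases with SNR and gamma shrinks the estimate", {
  set.seed(6)
  n <- 16
  grid <- conditioned_grid(n, seed = 6)
  istar <- matrix(0, n, n); istar[sample(n * n, 30)] <- runif(30, 0.5, 1)
  b0 <- forward_shift_variant(istar, grid)
  errs <- vapply(c(50, 500, 5000), function(ps) {
    bn <- add_sensor_noise(b0, photon_scale = ps, read_sigma = 0, seed = 7,
                           bit_depth = NULL)
    est <- fista_reconstruct(pmax(bn, 0), grid,
                             recon_config(gamma = 1e-4, max_iter = 300,
                                          tol = 0, background = FALSE))
    rel_err(est$image, istar)
  }, 0)
  expect_true(all(diff(errs) < 0))

  # shrinkage: as gamma grows large the estimate vanishes
  norms <- vapply(c(1e-4, 1, 1e4), function(gam) {
    est <- fista_reconstruct(b0, grid,
                             recon_config(gamma = gam, max_iter = 200, tol = 0,
                                          background = FALSE))
    sqrt(sum(est$image^2))
  }, 0)
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], 1e-2 * norms[1])
})

test_that("digital refocusing picks the simulation depth and breaks ties to the smallest", {
  set.seed(7)
  # calibration-style PSF stack simulated from a designed mask at 20 um
  # depth intervals around the working distance
  f <- generate_perlin_noise(192, 2, 16, seed = 5)
  pat <- contour_from_noise(f, pattern_width = 6)
  mk <- suppressWarnings(design_phase_mask(pat, distance = 1, n_iter = 15,
                                           seed = 1, pixel_pitch = 2))
  depths <- seq(1.96, 2.04, by = 0.02)
  k <- 41
  psfs <- array(0, c(length(depths), 1, 1, k, k))
  for (j in seq_along(depths))
    psfs[j, 1, 1, , ] <- suppressWarnings(
      simulate_psf(mk, depth = depths[j], crop = c(k, k)))
  grid <- psf_grid(psfs, depths = depths, grid_rows = 16, grid_cols = 16)
  n <- 32
  scene <- matrix(0, n, n)
  scene[sample(n * n, 40)] <- runif(40, 0.5, 1)
  p_true <- matrix(psfs[3, 1, 1, , ], k, k)   # simulated at 2.00 mm
  b <- forward_shift_invariant(scene, p_true)
  b <- add_sensor_noise(b, photon_scale = 1e5, read_sigma = 1e-4, seed = 1,
                        bit_depth = NULL)
  rf <- refocus(pmax(b, 0), grid, roi = c(5, 28, 5, 28))
  expect_equal(rf$best_depth, 2.0)

  # identical PSFs at all depths -> identical images -> smallest depth wins
  psfs_tie <- psfs
  for (j in seq_along(depths)) psfs_tie[j, 1, 1, , ] <- psfs[3, 1, 1, , ]
  grid_tie <- psf_grid(psfs_tie, depths = depths, grid_rows = 16, grid_cols = 16)
  rf_tie <- refocus(pmax(b, 0), grid_tie)
  expect_equal(rf_tie$best_depth, depths[1])

  expect_error(refocus(b, grid, roi = c(0, 40, 1, 10)), "roi")
})
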