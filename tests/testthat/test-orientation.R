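# theta grid spanning [0, 180) uniformly: makes the cosine-map identities
# exact (the double-angle moments vanish by symmetry)
theta_grid <- function(n = 60) {
  matrix(seq(0, 180, length.out = n * n + 1)[-(n * n + 1)], n, n)
}

test_that("harmonic amplitude follows the sinusoid convention and a projection oracle", {
  fs <- 20; n <- 40
  tt <- (0:(n - 1)) / fs
  v <- array(0, c(n, 2, 2))
  v[, 1, 1] <- 0.03 * cos(2 * pi * 4 * tt)
  v[, 2, 2] <- 5                       # constant trace
  amp <- harmonic_amplitude(v, 4, fs)
  expect_equal(amp[1, 1], 0.03, tolerance = 1e-9)
  expect_lt(amp[2, 2], 1e-12)

  # random traces against a direct complex-exponential dot product
  set.seed(1)
  vr <- array(rnorm(n * 3 * 3), c(n, 3, 3))
  ar <- harmonic_amplitude(vr, 4, fs)
  for (y in 1:3) for (x in 1:3) {
    oracle <- 0
    for (t in 1:n)
      oracle <- oracle + vr[t, y, x] * exp(-2i * pi * 4 * (t - 1) / fs)
    expect_lt(abs(ar[y, x] - Mod(oracle) * 2 / n), 1e-12)
  }

  expect_warning(harmonic_amplitude(vr[1:37, , , drop = FALSE], 4, fs), "DFT grid")
  expect_error(harmonic_amplitude(vr, 11, fs), "Nyquist")
})

test_that("RMS ROI thresholds at one-third of the maximum", {
  u <- matrix(1, 8, 8)
  expect_true(all(rms_roi(list(u))))
  # planted two-level map: high = 3u, low = 0.9u; threshold = max/3 = u
  m <- matrix(0.9, 10, 10); m[3:5, 3:5] <- 3
  mask <- rms_roi(list(m), threshold_frac = 1 / 3)
  expect_identical(mask, m == 3)
  expect_error(rms_roi(list(matrix(0, 4, 4))), "all-zero")
  expect_identical(formals(rms_roi)$threshold_frac, quote(1 / 3))
})

test_that("spatial bandpass passes the column band, rejects DC, and attenuates out-of-band", {
  n <- 128; pitch <- 20      # 2.56 mm field of view
  xx <- outer(rep(1, n), seq_len(n))
  mk_wave <- function(f_cyc_mm) sin(2 * pi * f_cyc_mm * xx * pitch * 1e-3)
  # ~1.2 cycles/mm (3 cycles across the 2.56 mm field, exactly on a DFT
  # bin): inside the 0.8-2.5 band, amplitude preserved within 1%
  w <- mk_wave(3 / (n * pitch * 1e-3))
  out <- bandpass_spatial(w, 0.8, 2.5, pitch)
  expect_equal(max(abs(out)), max(abs(w)), tolerance = 0.01)

  # constant map: DC removed entirely
  cst <- matrix(4, n, n)
  expect_lt(max(abs(bandpass_spatial(cst, 0.8, 2.5, pitch))),
            1e-9 * max(cst))

  # 0.4 cycles/mm: stopband, attenuated by far more than 100x; the analytic
  # annulus response at that radius is exactly zero
  w_lo <- mk_wave(1 / (n * pitch * 1e-3))  # ~0.39 cycles/mm, one DFT cycle
  out_lo <- bandpass_spatial(w_lo, 0.8, 2.5, pitch)
  expect_lt(max(abs(out_lo)), max(abs(w_lo)) / 100)
  expect_equal(contourscope:::bandpass_response(0.39, 0.8, 2.5), 0)
  expect_equal(contourscope:::bandpass_response(1.2, 0.8, 2.5), 1)

  expect_error(bandpass_spatial(w, 0.8, 30, pitch), "Nyquist")
})

test_that("d-prime maps follow the pooled-SD formula", {
  set.seed(2)
  m0 <- matrix(rnorm(64), 8, 8); m90 <- matrix(rnorm(64), 8, 8)
  s0 <- matrix(runif(64, 0.5, 2), 8, 8); s90 <- matrix(runif(64, 0.5, 2), 8, 8)
  dp <- dprime_map(m0, m90, s0, s90)
  for (k in 1:64)
    expect_lt(abs(dp[k] - (m0[k] - m90[k]) / sqrt((s0[k]^2 + s90[k]^2) / 2)),
              1e-12)
  expect_true(all(dprime_map(m0, m0, s0, s90) == 0))
  # unit effect: mean difference equal to the common SD gives d' = 1
  sig <- matrix(2, 8, 8)
  expect_true(all(abs(dprime_map(m0 + 2, m0, sig, sig) - 1) < 1e-12))
  # zero pooled SD handled
  z <- matrix(0, 8, 8)
  dp0 <- dprime_map(m0, m90, z, z)
  expect_true(all(dp0 == 0))
  expect_identical(attr(dp0, "n_zero_sd"), 64L)
})

test_that("decoder reduces to the per-pixel d-prime on one pixel and to the matched-filter SNR", {
  set.seed(3)
  # one-pixel ROI: decision-variable d' equals the pixel d'
  n_tr <- 400
  x0 <- rnorm(n_tr, 1, 1); x90 <- rnorm(n_tr, 0, 1)
  maps0 <- lapply(x0, function(v) matrix(v, 1, 1))
  maps90 <- lapply(x90, function(v) matrix(v, 1, 1))
  res1 <- decode_orientation(maps0, maps90, cv = "none")
  dp_direct <- (mean(x0) - mean(x90)) /
               sqrt((stats::var(x0) + stats::var(x90)) / 2)
  # with population weights the DV is a monotone transform of the pixel
  expect_equal(abs(res1$dprime_dv), abs(dp_direct), tolerance = 1e-9)

  # matched-filter identity: independent unit-variance pixels with planted
  # per-pixel d'_i and population weights give d'_DV = sqrt(sum d'_i^2)
  npx <- 64; n_tr <- 2000
  dtrue <- runif(npx, 0, 1)
  maps0 <- lapply(seq_len(n_tr), function(t) matrix(rnorm(npx, dtrue, 1), 8, 8))
  maps90 <- lapply(seq_len(n_tr), function(t) matrix(rnorm(npx, 0, 1), 8, 8))
  res <- decode_orientation(maps0, maps90, weights = matrix(dtrue, 8, 8))
  expect_equal(res$dprime_dv, sqrt(sum(dtrue^2)), tolerance = 0.05)

  expect_error(decode_orientation(maps0[1:2], maps90[1:2], cv = "loo"),
               "at least 3")
})

test_that("decoder is unbiased under a planted null with leave-one-out CV", {
  set.seed(4)
  nulls <- vapply(1:100, function(r) {
    m0 <- lapply(1:10, function(t) matrix(rnorm(16), 4, 4))
    m90 <- lapply(1:10, function(t) matrix(rnorm(16), 4, 4))
    decode_orientation(m0, m90, cv = "loo")$dprime_dv
  }, 0)
  se <- stats::sd(nulls) / sqrt(100)
  expect_lt(abs(mean(nulls)), 3 * se)
})

test_that("pairwise correlations of ideal cosine maps equal cos(2 delta)", {
  th <- theta_grid(40)
  orientations <- c(0, 30, 60, 90, 120, 150)
  maps <- lapply(orientations, function(o) cospi(2 * (th - o) / 180))
  curve <- pairwise_map_correlation(maps, orientations)
  expect_identical(curve$delta, c(30, 60, 90))
  expect_equal(curve$r_mean, cospi(2 * c(30, 60, 90) / 180), tolerance = 1e-6)
  # monotone decreasing over the sampled differences
  expect_true(all(diff(curve$r_mean) < 0))

  # self and negated-self correlations
  expect_equal(pairwise_map_correlation(list(maps[[1]], maps[[1]]),
                                        c(0, 0))$r_mean, 1, tolerance = 1e-12)
  expect_equal(pairwise_map_correlation(list(maps[[1]], -maps[[1]]),
                                        c(0, 90))$r_mean, -1, tolerance = 1e-12)

  # both pairs involving the flat map warn and are skipped
  expect_warning(expect_warning(
    curve_skip <- pairwise_map_correlation(
      list(maps[[1]], maps[[2]], matrix(1, 40, 40)), c(0, 30, 60)),
    "zero-variance"), "zero-variance")
  expect_identical(curve_skip$delta, 30)   # only the valid pair remains
})

test_that("vector summation recovers planted preferences and flags isotropic pixels", {
  th <- theta_grid(30)
  orientations <- c(0, 30, 60, 90, 120, 150)
  maps <- lapply(orientations, function(o) cospi(2 * (th - o) / 180))
  comp <- composite_orientation_map(maps, orientations)
  err <- abs(comp$pref_map - th)
  err <- pmin(err, 180 - err)
  expect_lt(max(err), 1)

  # pixel responding at a single orientation
  one <- lapply(orientations, function(o) matrix(as.numeric(o == 60), 2, 2))
  c1 <- composite_orientation_map(one, orientations)
  expect_true(all(abs(c1$pref_map - 60) < 1e-9))
  expect_true(all(abs(c1$magnitude_map - 1) < 1e-12))

  # equal response at all orientations: magnitude 0, preference masked to 0
  iso <- lapply(orientations, function(o) matrix(1, 2, 2))
  ci <- composite_orientation_map(iso, orientations)
  expect_true(all(ci$magnitude_map < 1e-12))
  expect_true(all(ci$pref_map == 0))
})

test_that("map comparison uses the sin(2 theta) encoding", {
  th <- theta_grid(20)
  expect_equal(compare_maps(th, th), 1, tolerance = 1e-12)
  expect_equal(compare_maps(th, (th + 90) %% 180), -1, tolerance = 1e-12)
  # smooth decrease with a global offset, symmetric about 90 degrees
  deltas <- c(0, 20, 45, 70, 90, 110, 160)
  rs <- vapply(deltas, function(d) compare_maps(th, (th + d) %% 180), 0)
  expect_equal(rs, cospi(2 * deltas / 180), tolerance = 1e-9)

  # random maps against a direct Pearson oracle
  set.seed(5)
  a <- matrix(runif(100, 0, 180), 10, 10)
  b <- matrix(runif(100, 0, 180), 10, 10)
  oracle <- stats::cor(sin(2 * a * pi / 180)[1:100], sin(2 * b * pi / 180)[1:100])
  expect_lt(abs(compare_maps(a, b) - oracle), 1e-12)

  expect_error(compare_maps(matrix(0, 4, 4), matrix(runif(16, 0, 180), 4, 4)),
               "constant")
})

test_that("shuffle null is bounded, reproduces the identity diagnostic, and matches exhaustion", {
  set.seed(6)
  th <- theta_grid(16)
  orientations <- c(0, 30, 60, 90, 120, 150)
  # noisy response maps so no exact symmetries remain
  maps <- lapply(orientations, function(o)
    cospi(2 * (th - o) / 180) + matrix(rnorm(256, 0, 0.3), 16, 16))
  ref <- composite_orientation_map(maps, orientations)$pref_map

  # forced identity permutation reproduces the unshuffled comparison
  sid <- shuffle_null(maps, orientations, ref,
                      permutations = matrix(1:6, 1))
  expect_equal(sid$r[1], compare_maps(ref, ref), tolerance = 1e-12)

  sn <- shuffle_null(maps, orientations, ref, n_shuffles = 300, seed = 7)
  expect_true(all(sn$r >= -1 & sn$r <= 1))
  expect_equal(sn$mean, mean(sn$r))

  # exhaustive enumeration over all 720 label permutations vs the sampled
  # null: means agree within Monte-Carlo error (3 SE), after removing the
  # encoding-equivalent relabelings the sampler excludes
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  keep <- !apply(perms, 1, function(p) {
    all(orientations[p] == orientations) ||
      all((orientations[p] %% 180) == ((90 - orientations) %% 180))
  })
  ex <- shuffle_null(maps, orientations, ref, permutations = perms[keep, ])
  se <- stats::sd(sn$r) / sqrt(length(sn$r))
  expect_lt(abs(mean(sn$r) - mean(ex$r)), 3 * se)
})
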