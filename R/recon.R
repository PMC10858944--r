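# Scene reconstruction: closed-form Wiener/Tikhonov deconvolution, FISTA
# for the spatially varying model with a jointly estimated low-frequency
# (DCT-constrained) background, and sharpness-based digital refocusing.

#' Reconstruction configuration
#'
#' @param gamma Tikhonov weight; `NULL` selects `0.01 * max |F(p)|^2` of the
#'   central PSF at reconstruction time.
#' @param model `"shift_variant"` or `"shift_invariant"` (metadata; the
#'   operator follows the PSF grid).
#' @param max_iter,tol FISTA iteration cap and relative-objective stopping
#'   tolerance.
#' @param dct_keep size of the retained lowest-frequency DCT block of the
#'   background (the in-vivo processing keeps 5 x 5).
#' @param nonneg clip the scene at zero each iteration.
#' @param background jointly estimate the low-frequency background `g`
#'   (`FALSE` pins `g = 0`).
#' @param depth reconstruction depth in mm, or `"auto"` to refocus.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(gamma = NULL, model = c("shift_variant", "shift_invariant"),
                         max_iter = 200L, tol = 1e-8, dct_keep = 5L,
                         nonneg = TRUE, background = TRUE, depth = "auto") {
  model <- match.arg(model)
  if (!is.null(gamma) && gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (dct_keep < 1) stop("`dct_keep` must be >= 1", call. = FALSE)
  structure(list(gamma = gamma, model = model, max_iter = as.integer(max_iter),
                 tol = tol, dct_keep = as.integer(dct_keep), nonneg = nonneg,
                 background = background, depth = depth),
            class = "recon_config")
}

#' Wiener/Tikhonov deconvolution
#'
#' Closed-form frequency-domain solution
#' \eqn{\hat i = F^{-1}( \overline{F(p)} \odot F(b) / (|F(p)|^2 + \gamma) )}
#' computed on the same zero-padded grid and with the same centering
#' convention as [forward_shift_invariant()], so that a noiseless
#' interior-supported measurement is inverted exactly in the small-`gamma`
#' limit.
#'
#' @param b measurement matrix (sensor frame).
#' @param psf PSF matrix (need not be normalized, must be nonzero).
#' @param gamma Tikhonov weight (>= 0); `gamma = 0` requires a PSF with no
#'   spectral zeros on the padded grid.
#' @return real matrix of the measurement's size.
#' @export
wiener_reconstruct <- function(b, psf, gamma = NULL) {
  if (all(psf == 0)) stop("`psf` must be nonzero", call. = FALSE)
  plan <- conv_plan(dim(b), dim(psf))
  otf <- psf_otf(psf, plan)
  pow <- Mod(otf)^2
  if (is.null(gamma)) gamma <- 0.01 * max(pow)
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (gamma == 0 && min(pow) < .Machine$double.eps * max(pow))
    stop("gamma = 0 with PSF spectral zeros: closed form is not defined",
         call. = FALSE)
  B <- fft2(pad_at(b, plan$py, plan$px, plan$cy, plan$cx))
  I <- ifft2(Conj(otf) * B / (pow + gamma))
  Re(I[1:plan$ny, 1:plan$nx])
}

#' Project an image onto the low-frequency DCT subspace
#'
#' Type-II orthonormal 2-D DCT, zeroing every coefficient `(u, v)` with
#' `u >= keep` or `v >= keep` (0-based), inverse transform.  With
#' `keep = 5` this is the background constraint of the joint reconstruction:
#' only the 5 x 5 lowest-frequency block survives.
#'
#' @param g numeric matrix.
#' @param keep side of the retained coefficient block
#'   (`keep <= min(dim(g))`).
#' @return matrix of the same size.
#' @export
dct_background_project <- function(g, keep = 5L) {
  if (keep > min(dim(g))) stop("`keep` exceeds image size", call. = FALSE)
  Cr <- dct_matrix(nrow(g)); Cc <- dct_matrix(ncol(g))
  G <- dct2(g, Cr, Cc)
  G[-seq_len(keep), ] <- 0
  G[, -seq_len(keep)] <- 0
  idct2(G, Cr, Cc)
}

# Largest eigenvalue of the joint Hessian
#   H (i, g) = (2 Phi^T Phi i + 2 Phi^T g + gamma i, 2 Phi i + 2 g)
# by power iteration (deterministic start).
fista_lipschitz <- function(svp, gamma, n_iter = 30) {
  p <- svp$plan
  i <- matrix(1, p$ny, p$nx); g <- matrix(1, p$ny, p$nx)
  i[1, 1] <- 2  # break symmetry
  L <- 1
  for (it in seq_len(n_iter)) {
    nrm <- sqrt(sum(i^2) + sum(g^2))
    i <- i / nrm; g <- g / nrm
    Fi <- apply_forward_sv(i, svp)
    hi <- 2 * apply_adjoint_sv(Fi + g, svp) + gamma * i
    hg <- 2 * (Fi + g)
    L <- sqrt(sum(hi^2) + sum(hg^2))
    i <- hi; g <- hg
  }
  L
}

#' FISTA reconstruction with joint low-frequency background
#'
#' Minimizes \eqn{\|(\Phi i + g) - b\|_2^2 + (\gamma/2)\|i\|_2^2} over a
#' nonnegative scene \eqn{i} and a background \eqn{g} confined to the
#' lowest-frequency DCT block, using FISTA with step `1/L` (`L` from power
#' iteration on the joint Hessian), projections applied every iteration,
#' and momentum restarts whenever the objective increases (so the recorded
#' objective trace is non-increasing).
#'
#' @param b measurement matrix.
#' @param grid a `psf_grid` (a 1 x 1 grid gives the shift-invariant model).
#' @param config a [recon_config()].
#' @param init optional list with starting `image` and `background` (e.g.
#'   the previous frame's estimate when reconstructing a video).
#' @param op optional precomputed operator plan from an earlier call (field
#'   `op` of a previous `scene_estimate`); reusing it across the frames of
#'   a stack avoids recomputing window/OTF tables and the step size.
#' @return object of class `scene_estimate` with fields `image`,
#'   `background`, `depth`, `objective_trace`, `iterations`, `converged`,
#'   `gamma`, `op`.
#' @export
fista_reconstruct <- function(b, grid, config = recon_config(), init = NULL,
                              op = NULL) {
  depth <- if (identical(config$depth, "auto")) grid$depths[1] else config$depth
  svp <- if (!is.null(op)) op$svp else shift_variant_plan(grid, depth, dim(b))
  gamma <- config$gamma
  if (is.null(gamma)) {
    ctr <- c(ceiling(length(grid$grid_rows) / 2), ceiling(length(grid$grid_cols) / 2))
    pk <- psf_plane(grid, depth)
    p0 <- matrix(pk[ctr[1], ctr[2], , ], dim(pk)[3], dim(pk)[4])
    gamma <- 0.01 * max(Mod(psf_otf(p0, svp$plan))^2)
  }
  L <- if (!is.null(op)) op$L else fista_lipschitz(svp, gamma)
  s <- 1 / L
  Cr <- dct_matrix(nrow(b)); Cc <- dct_matrix(ncol(b))
  keep <- min(config$dct_keep, nrow(b), ncol(b))
  proj_g <- function(g) {
    if (!config$background) return(matrix(0, nrow(b), ncol(b)))
    G <- dct2(g, Cr, Cc)
    G[-seq_len(keep), ] <- 0; G[, -seq_len(keep)] <- 0
    idct2(G, Cr, Cc)
  }
  proj_i <- if (config$nonneg) function(i) pmax(i, 0) else identity

  zero <- matrix(0, nrow(b), ncol(b))
  i_x <- if (!is.null(init$image)) init$image else zero
  g_x <- if (!is.null(init$background)) proj_g(init$background) else zero
  i_x <- proj_i(i_x)
  Fi_x <- apply_forward_sv(i_x, svp)
  obj <- function(Fi, g, i) sum((Fi + g - b)^2) + gamma / 2 * sum(i^2)
  f_x <- obj(Fi_x, g_x, i_x)

  i_old <- i_x; g_old <- g_x; Fi_old <- Fi_x
  t_k <- 1
  trace <- numeric(config$max_iter)
  converged <- FALSE
  iter_done <- 0L

  step_from <- function(i_y, g_y, Fi_y) {
    r <- Fi_y + g_y - b
    gi <- 2 * apply_adjoint_sv(r, svp) + gamma * i_y
    i_n <- proj_i(i_y - s * gi)
    g_n <- proj_g(g_y - s * 2 * r)
    Fi_n <- apply_forward_sv(i_n, svp)
    list(i = i_n, g = g_n, Fi = Fi_n, f = obj(Fi_n, g_n, i_n))
  }

  for (k in seq_len(config$max_iter)) {
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    beta <- (t_k - 1) / t_new
    i_y <- i_x + beta * (i_x - i_old)
    g_y <- g_x + beta * (g_x - g_old)
    Fi_y <- (1 + beta) * Fi_x - beta * Fi_old   # linearity of Phi
    st <- step_from(i_y, g_y, Fi_y)
    if (!is.finite(st$f))
      stop(sprintf("FISTA diverged (objective not finite) at step size %g", s),
           call. = FALSE)
    if (st$f > f_x + 1e-12 * abs(f_x)) {
      # momentum restart: plain proximal-gradient step from the last iterate
      t_new <- 1
      st <- step_from(i_x, g_x, Fi_x)
    }
    i_old <- i_x; g_old <- g_x; Fi_old <- Fi_x
    i_x <- st$i; g_x <- st$g; Fi_x <- st$Fi
    rel <- abs(f_x - st$f) / max(abs(f_x), .Machine$double.eps)
    f_x <- st$f
    t_k <- t_new
    trace[k] <- f_x
    iter_done <- k
    if (rel < config$tol) { converged <- TRUE; break }
  }

  structure(list(image = i_x, background = g_x, depth = depth,
                 objective_trace = trace[seq_len(iter_done)],
                 iterations = iter_done, converged = converged,
                 gamma = gamma, config = config,
                 op = list(svp = svp, L = L)),
            class = "scene_estimate")
}

#' @export
print.scene_estimate <- function(x, ...) {
  cat(sprintf("<scene_estimate> %d x %d px at depth %g mm\n",
              nrow(x$image), ncol(x$image), x$depth))
  cat(sprintf("  %d iterations, objective %.6g, gamma %.3g, converged: %s\n",
              x$iterations, utils::tail(x$objective_trace, 1), x$gamma,
              x$converged))
  invisible(x)
}

#' @export
plot.scene_estimate <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(x$image[nrow(x$image):1, ]), col = grDevices::gray.colors(256),
                  axes = FALSE, main = "scene", ...)
  graphics::plot(x$objective_trace, type = "l", log = "y", xlab = "iteration",
                 ylab = "objective", main = "FISTA objective")
  invisible(x)
}

# variance of the Laplacian within an roi = c(r1, r2, c1, c2)
laplacian_sharpness <- function(img, roi) {
  lap <- conv_same(img, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  stats::var(as.vector(lap[roi[1]:roi[2], roi[3]:roi[4]]))
}

#' Digital refocusing
#'
#' Reconstructs the measurement at each candidate depth (fast shift-invariant
#' Wiener deconvolution with the central PSF of that depth) and scores each
#' reconstruction by the variance of its Laplacian inside the region of
#' interest; the sharpest depth wins, ties broken to the smallest depth.
#'
#' @param b measurement matrix.
#' @param psf_stack a `psf_grid` with at least two depths (typically the
#'   20-um-interval calibration stack).
#' @param depths candidate depths in mm (default: all calibrated depths).
#' @param roi integer vector `(r1, r2, c1, c2)` of the focus region.
#' @param gamma Tikhonov weight passed to the Wiener solver.
#' @return list with `best_depth`, `sharpness` (named per depth), and
#'   `images` (one reconstruction per depth).
#' @export
refocus <- function(b, psf_stack, depths = psf_stack$depths, roi = NULL,
                    gamma = NULL) {
  if (length(depths) < 2) stop("need at least 2 candidate depths", call. = FALSE)
  if (is.null(roi)) roi <- c(1, nrow(b), 1, ncol(b))
  if (roi[1] < 1 || roi[2] > nrow(b) || roi[3] < 1 || roi[4] > ncol(b) ||
      roi[1] > roi[2] || roi[3] > roi[4])
    stop("`roi` outside the image", call. = FALSE)
  depths <- sort(depths)
  ctr <- c(ceiling(length(psf_stack$grid_rows) / 2),
           ceiling(length(psf_stack$grid_cols) / 2))
  imgs <- vector("list", length(depths))
  sharp <- numeric(length(depths))
  for (j in seq_along(depths)) {
    pk <- psf_plane(psf_stack, depths[j])
    p0 <- matrix(pk[ctr[1], ctr[2], , ], dim(pk)[3], dim(pk)[4])
    imgs[[j]] <- wiener_reconstruct(b, p0, gamma)
    sharp[j] <- laplacian_sharpness(imgs[[j]], roi)
  }
  names(sharp) <- format(depths)
  list(best_depth = depths[which.max(sharp)], sharpness = sharp, images = imgs)
}
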