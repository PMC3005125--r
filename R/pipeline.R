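# Coarse-to-fine multiscale driver: downsample, iterate
# warp -> update -> accumulate -> regularize with an SSD stopping rule,
# upsample the field, repeat to the finest scale.

#' Downsample a volume for the multiscale pyramid
#'
#' Gaussian antialias smoothing (standard deviation `kappa^j / 2` voxels,
#' boundary-renormalized so constants are preserved) followed by decimation
#' by `kappa^j`, keeping every `kappa^j`-th voxel starting at the first.
#' `j = 0` returns the input unchanged.
#'
#' @param v 2D or 3D numeric array.
#' @param j Scale index (0 = finest).
#' @param kappa Subsampling factor between consecutive scales (default 2).
#' @return The downsampled array.
#' @export
downsample_volume <- function(v, j, kappa = 2L) {
  .check_image(v, "v")
  j <- as.integer(j)
  if (j < 0) stop("j must be non-negative", call. = FALSE)
  if (j == 0L) return(v)
  step <- as.integer(kappa)^j
  if (any(dim(v) %/% step < 2L))
    stop("volume too small for the requested scale", call. = FALSE)
  sm <- .gauss_smooth(v, sd = step / 2, renormalized = TRUE)
  idx <- lapply(dim(v), function(n) seq(1L, n, by = step))
  do.call(`[`, c(list(sm), idx, list(drop = FALSE)))
}

# Target shape of scale-j grids for a full-resolution shape.
.scale_shape <- function(shape, j, kappa = 2L) {
  if (j == 0L) return(as.integer(shape))
  step <- as.integer(kappa)^j
  as.integer((shape - 1L) %/% step + 1L)
}

#' Upsample a displacement field to the next finer scale
#'
#' Linear interpolation of every component onto the `kappa` times finer grid
#' and multiplication of the vector values by `kappa`, converting coarse
#' voxel units into fine voxel units. A fine-grid voxel `i` corresponds to
#' coarse-grid position `(i - 1)/kappa + 1`.
#'
#' @param D Displacement field on the coarse grid.
#' @param kappa Upsampling factor (default 2).
#' @param target_shape Optional shape of the fine grid (defaults to
#'   `kappa * (shape - 1) + 1` rounded up to cover the fine extent).
#' @param rescale Multiply the vector values by `kappa` (`TRUE` for
#'   displacement fields; `FALSE` when transporting certainty maps, which
#'   carry values, not voxel offsets — see [upsample_map()]).
#' @return The field on the fine grid.
#' @export
upsample_field <- function(D, kappa = 2L, target_shape = NULL, rescale = TRUE) {
  .check_field(D, "D")
  kappa <- as.integer(kappa)
  if (kappa < 2L) stop("kappa must be >= 2", call. = FALSE)
  shape <- .field_shape(D)
  nd <- length(shape)
  if (is.null(target_shape)) target_shape <- kappa * (shape - 1L) + 1L
  target_shape <- as.integer(target_shape)
  coords <- .grid_coords(target_shape)
  mode(coords) <- "double"
  for (a in seq_len(nd)) coords[, a] <- (coords[, a] - 1) / kappa + 1
  out <- array(0, c(target_shape, nd))
  fac <- if (rescale) kappa else 1
  for (a in seq_len(nd))
    out <- .set_field_comp(out, a,
      array(fac * .interp_linear(.field_comp(D, a), coords), target_shape))
  out
}

#' Upsample a scalar map (e.g. a certainty map) to a finer grid
#'
#' Linear interpolation onto the `kappa` times finer grid, without any value
#' rescaling.
#'
#' @param m Scalar array on the coarse grid.
#' @param kappa Upsampling factor.
#' @param target_shape Shape of the fine grid.
#' @return The interpolated array.
#' @export
upsample_map <- function(m, kappa = 2L, target_shape = NULL) {
  .check_image(m, "m")
  shape <- dim(m)
  nd <- length(shape)
  kappa <- as.integer(kappa)
  if (is.null(target_shape)) target_shape <- kappa * (shape - 1L) + 1L
  target_shape <- as.integer(target_shape)
  coords <- .grid_coords(target_shape)
  mode(coords) <- "double"
  for (a in seq_len(nd)) coords[, a] <- (coords[, a] - 1) / kappa + 1
  array(.interp_linear(m, coords), target_shape)
}

#' Multiscale nonparametric registration
#'
#' Estimates the displacement field `Da` such that the moving image warped by
#' it matches the fixed image: `m(x + Da(x)) ~ f(x)`. Both images are
#' decomposed into a Gaussian pyramid; at each scale, from coarse to fine,
#' the loop iterates (i) warping `w = m_j(x + Da(x))`, (ii) field
#' computation (phase-based [morphons_update()] or intensity-based
#' [demons_update()]), (iii) accumulation ([accumulate_field()] in additive,
#' compositive or diffeomorphic mode, certainty-damped for Morphons), and
#' (iv) regularization ([regularize_field()]; plain boundary-renormalized
#' Gaussian smoothing for Demons, which carries no certainty). Iteration at
#' a scale stops after at least `min_iters` iterations once the relative SSD
#' change drops below `ssd_rel_tol`, or at `max_iters`. Between scales the
#' field is upsampled; the certainty map restarts from zero at every scale
#' (certainties of differently downsampled images are not commensurate).
#'
#' The number of scales is capped automatically so that the coarsest grid
#' keeps at least `2 * kernel_size` voxels per axis. The same filter bank is
#' applied at every scale: filtering the downsampled images realizes the
#' doubling of the probed frequency from scale to scale.
#'
#' @param fixed,moving 2D or 3D numeric arrays of identical shape.
#' @param method `"morphons"` (local phase) or `"demons"` (intensity).
#' @param accumulation `"diffeomorphic"` (default), `"additive"` or
#'   `"compositive"`.
#' @param scales Requested coarsest scale index J (scales `J..0` are
#'   visited); capped by the grid size. Default 8.
#' @param kappa Subsampling factor between scales (default 2).
#' @param sigma_psi_sq Variance (voxels^2) of the regularization Gaussian
#'   (default 2).
#' @param min_iters,max_iters Iteration bounds per scale (defaults 10, 20).
#' @param ssd_rel_tol Relative SSD change below which iteration stops once
#'   `min_iters` is reached (default 1e-4, i.e. 0.01 percent).
#' @param rho Quadrature bank center frequency (default `pi/2`).
#' @param kernel_size Quadrature kernel extent (default 9).
#' @param max_step Scaling threshold of [exp_field()] (default 0.5 voxels).
#' @param verbose Print per-iteration progress.
#' @return An object of class `registration`: list with `field` (finest-grid
#'   displacement field), `certainty`, `log` (data.frame with per-scale,
#'   per-iteration `scale`, `iter`, `ssd`, `harmonic_energy`,
#'   `min_jacobian`), and the call parameters.
#' @examples
#' f <- matrix(0, 48, 48)
#' f[16:32, 16:32] <- 1
#' f <- morphons:::.gauss_smooth(f, 2)
#' reg <- register_volumes(f, f, method = "morphons", scales = 1,
#'                         min_iters = 2, max_iters = 2)
#' max(abs(reg$field)) < 0.1
#' @export
register_volumes <- function(fixed, moving,
                             method = c("morphons", "demons"),
                             accumulation = c("diffeomorphic", "additive", "compositive"),
                             scales = 8L, kappa = 2L, sigma_psi_sq = 2,
                             min_iters = 10L, max_iters = 20L,
                             ssd_rel_tol = 1e-4, rho = pi / 2,
                             kernel_size = 9L, max_step = 0.5,
                             verbose = FALSE) {
  method <- match.arg(method)
  accumulation <- match.arg(accumulation)
  .check_image(fixed, "fixed")
  .check_image(moving, "moving")
  if (!identical(dim(fixed), dim(moving)))
    stop("fixed and moving must have identical shapes (resample first)", call. = FALSE)
  if (min_iters > max_iters || min_iters < 1L)
    stop("need 1 <= min_iters <= max_iters", call. = FALSE)
  if (ssd_rel_tol <= 0) stop("ssd_rel_tol must be positive", call. = FALSE)
  kappa <- as.integer(kappa)
  if (kappa < 2L) stop("kappa must be >= 2", call. = FALSE)

  shape <- dim(fixed)
  nd <- length(shape)
  # cap J: coarsest grid must keep >= kernel_size voxels per axis. The
  # truncated kernels' effective width is ~1/rho voxels, so filtering stays
  # meaningful down to kernel-sized grids, and the deep coarse scales are
  # what give the pyramid its large-displacement capture range.
  J <- as.integer(scales)
  while (J > 0L && any(.scale_shape(shape, J, kappa) < kernel_size))
    J <- J - 1L
  bank <- if (method == "morphons") loglet_bank(rho, nd, kernel_size) else NULL

  Da <- NULL
  ca <- NULL
  log_rows <- list()
  for (j in J:0) {
    fj <- downsample_volume(fixed, j, kappa)
    mj <- downsample_volume(moving, j, kappa)
    tgt <- dim(fj)
    if (is.null(Da)) {
      Da <- .zero_field(tgt)
    } else {
      Da <- upsample_field(Da, kappa, target_shape = tgt)
    }
    # certainty restarts at every scale: amplitudes of differently
    # downsampled images are not commensurate, and the first accumulation at
    # a new scale should be undamped (weight c_u/(0 + c_u) = 1)
    ca <- array(0, tgt)
    rf <- if (method == "morphons") apply_bank(fj, bank) else NULL
    ssd_prev <- NA_real_
    for (iter in seq_len(max_iters)) {
      w <- warp_volume(mj, Da)
      if (method == "morphons") {
        upd <- .morphons_update_resp(rf, w, bank)
        Da <- accumulate_field(Da, upd$field, ca, upd$certainty,
                               mode = accumulation, max_step = max_step)
        ca <- accumulate_certainty(ca, upd$certainty)
        reg <- regularize_field(Da, ca, sigma_psi_sq)
        Da <- reg$field
        ca <- reg$certainty
      } else {
        upd <- demons_update(fj, w)
        Da <- accumulate_field(Da, upd$field, mode = accumulation,
                               max_step = max_step)
        ones <- array(1, tgt)
        Da <- regularize_field(Da, ones, sigma_psi_sq)$field
      }
      ssd_now <- ssd(fj, mj, Da)
      jac <- jacobian_determinant(Da)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        scale = j, iter = iter, ssd = ssd_now,
        harmonic_energy = harmonic_energy(Da), min_jacobian = min(jac))
      if (verbose)
        message(sprintf("scale %d iter %2d: ssd %.6g  minJ % .4f",
                        j, iter, ssd_now, min(jac)))
      if (iter >= min_iters && ssd_now == 0) break
      if (iter >= min_iters && is.finite(ssd_prev) && ssd_prev > 0 &&
          abs(ssd_now - ssd_prev) / ssd_prev < ssd_rel_tol) break
      ssd_prev <- ssd_now
    }
  }
  structure(list(field = Da, certainty = ca,
                 log = do.call(rbind, log_rows),
                 method = method, accumulation = accumulation,
                 scales = J, kappa = kappa, sigma_psi_sq = sigma_psi_sq,
                 rho = rho, kernel_size = kernel_size),
            class = "registration")
}

#' @export
print.registration <- function(x, ...) {
  fin <- x$log[nrow(x$log), ]
  cat(sprintf("%s registration (%s accumulation), %d+1 scales\n",
              x$method, x$accumulation, x$scales))
  cat(sprintf("  final SSD %.6g, harmonic energy %.6g, min Jacobian %.4f\n",
              fin$ssd, fin$harmonic_energy, fin$min_jacobian))
  cat(sprintf("  max |field| %.3f voxels, %d iterations logged\n",
              .field_max_norm(x$field), nrow(x$log)))
  invisible(x)
}
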