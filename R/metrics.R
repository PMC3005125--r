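# Evaluation metrics: image matching, field smoothness, invertibility,
# landmark accuracy, mask volume change, mutual information.

#' Sum of squared differences between fixed and warped moving image
#'
#' `sum_x (f(x) - m(x + D(x)))^2` over all voxels. With `D = NULL` no
#' warping is applied.
#'
#' @param f Fixed image.
#' @param m Moving image, same shape.
#' @param D Optional displacement field on the fixed grid.
#' @return A non-negative scalar.
#' @export
ssd <- function(f, m, D = NULL) {
  .check_image(f, "f")
  .check_image(m, "m")
  if (!identical(dim(f), dim(m)))
    stop("f and m must share a grid", call. = FALSE)
  w <- if (is.null(D)) m else warp_volume(m, D)
  sum((f - w)^2)
}

#' Harmonic energy of a displacement field
#'
#' Half the sum over voxels of the squared gradient norms of every field
#' component, `0.5 * sum_x sum_i |grad d_i(x)|^2`, a measure of how far the
#' field is from a constant (rigid translation): smoother fields have lower
#' energy. Gradients use centered differences in the interior and one-sided
#' differences at the boundary.
#'
#' @param D Displacement field.
#' @return A non-negative scalar.
#' @export
harmonic_energy <- function(D) {
  .check_field(D, "D")
  nd <- .field_ndim(D)
  e <- 0
  for (i in seq_len(nd)) {
    di <- .field_comp(D, i)
    for (j in seq_len(nd)) e <- e + sum(.grad_axis(di, j)^2)
  }
  e / 2
}

#' Count inverted (negative-Jacobian) voxels
#'
#' Number of voxels where the Jacobian determinant of `Id + D` is negative,
#' i.e. where the deformation folds the grid. Any positive count disqualifies
#' the field as a physical deformation.
#'
#' @param D Displacement field.
#' @return An integer count.
#' @export
count_inverted <- function(D) {
  sum(jacobian_determinant(D) < 0)
}

#' Landmark registration error
#'
#' For paired landmark lists (voxel coordinates, 1-based, same order), the
#' per-point Euclidean error in millimetres between the moving landmark and
#' the fixed landmark displaced by the field:
#' `|| (p_m - (p_f + D(p_f))) * spacing ||`. The field is sampled at the
#' fixed landmarks by linear interpolation.
#'
#' @param p_fixed,p_moving Numeric matrices, one landmark per row, `ndim`
#'   columns, equal row counts.
#' @param D Displacement field on the fixed grid.
#' @param spacing Voxel size per axis in mm (default all 1).
#' @return Numeric vector of per-point errors in mm.
#' @export
landmark_error <- function(p_fixed, p_moving, D, spacing = NULL) {
  .check_field(D, "D")
  p_fixed <- as.matrix(p_fixed)
  p_moving <- as.matrix(p_moving)
  nd <- .field_ndim(D)
  if (ncol(p_fixed) != nd || !identical(dim(p_fixed), dim(p_moving)))
    stop("landmark matrices must be paired with ndim columns", call. = FALSE)
  if (is.null(spacing)) spacing <- rep(1, nd)
  err2 <- 0
  for (a in seq_len(nd)) {
    da <- .interp_linear(.field_comp(D, a), p_fixed)
    err2 <- err2 + ((p_moving[, a] - (p_fixed[, a] + da)) * spacing[a])^2
  }
  sqrt(err2)
}

#' Volume change of a warped binary mask
#'
#' Warps a binary label mask by the field using nearest-neighbour
#' interpolation and reports the relative change in the number of foreground
#' voxels, `100 * (V_warped - V_original) / V_original` percent. Used to
#' check that a registration does not artificially shrink or inflate
#' delineated structures.
#'
#' @param mask Binary (0/1) array on the moving image grid.
#' @param D Displacement field on the fixed grid.
#' @return Percentage volume change (scalar).
#' @export
mask_volume_change <- function(mask, D) {
  .check_image(mask, "mask")
  if (!all(mask %in% c(0, 1)))
    stop("mask must be binary", call. = FALSE)
  v0 <- sum(mask != 0)
  if (v0 == 0) stop("mask is empty", call. = FALSE)
  w <- warp_volume(mask, D, interpolation = "nearest")
  100 * (sum(w != 0) - v0) / v0
}

#' Mutual information between two volumes
#'
#' Standard joint-histogram mutual information with `bins` equal-width bins
#' per image over each image's observed range, in bits (base-2 logarithm).
#' `MI(f, f)` equals the entropy of `f`'s histogram; independent images give
#' values near 0. Reported for evaluation only (never optimized).
#'
#' @param f,w Numeric arrays of identical shape.
#' @param bins Number of histogram bins per image (default 64).
#' @return A non-negative scalar (bits).
#' @export
mutual_information <- function(f, w, bins = 64L) {
  .check_image(f, "f")
  .check_image(w, "w")
  if (!identical(dim(f), dim(w)))
    stop("f and w must share a grid", call. = FALSE)
  bins <- as.integer(bins)
  bin_index <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) return(rep(1L, length(x)))
    i <- as.integer(floor((x - r[1]) / (r[2] - r[1]) * bins)) + 1L
    pmin(i, bins)
  }
  bi <- bin_index(as.vector(f))
  bj <- bin_index(as.vector(w))
  joint <- tabulate(bi + (bj - 1L) * bins, nbins = bins * bins) / length(bi)
  pj <- matrix(joint, bins, bins)
  pi_ <- rowSums(pj)
  pw <- colSums(pj)
  nz <- pj > 0
  outer_ <- outer(pi_, pw)
  sum(pj[nz] * log2(pj[nz] / outer_[nz]))
}
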