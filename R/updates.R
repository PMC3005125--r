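# Per-iteration field computation (Theta), accumulation (Phi) and
# regularization (Psi), in conventional and diffeomorphic variants.

# Smallest/largest eigenvalue of a field of symmetric 2x2 or 3x3 matrices,
# given the unique entries as arrays. Used for the singularity test of the
# per-voxel normal matrix.
.sym_eig_range2 <- function(m11, m12, m22) {
  tr <- m11 + m22
  disc <- sqrt(pmax((m11 - m22)^2 + 4 * m12^2, 0))
  list(min = (tr - disc) / 2, max = (tr + disc) / 2)
}

.sym_eig_range3 <- function(m11, m12, m13, m22, m23, m33) {
  q <- (m11 + m22 + m33) / 3
  p2 <- (m11 - q)^2 + (m22 - q)^2 + (m33 - q)^2 + 2 * (m12^2 + m13^2 + m23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  b11 <- m11 - q; b22 <- m22 - q; b33 <- m33 - q
  detB <- b11 * (b22 * b33 - m23^2) - m12 * (m12 * b33 - m23 * m13) +
          m13 * (m12 * m23 - b22 * m13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  emax <- q + 2 * p * cos(phi)
  emin <- q + 2 * p * cos(phi + 2 * pi / 3)
  list(min = emin, max = emax)
}

#' Per-voxel weighted least-squares phase solve
#'
#' Solves, independently at every voxel, for the displacement `d` minimizing
#' the certainty-weighted phase-matching energy
#' `sum_k (c_k * (rho * eta_k' d - dphi_k))^2` over the bank's K directions.
#' The closed-form minimizer is `d = (N' C^2 N)^{-1} N' C^2 Gamma / rho` with
#' `N` the direction matrix, `C = diag(c_k)` and `Gamma = (dphi_k)`. Where
#' the normal matrix is numerically singular (smallest eigenvalue below
#' `1e-9` times the largest, or all certainties below `1e-12` of the global
#' maximum), `d` is set to 0.
#'
#' @param dphi List of K numeric arrays (or K-vectors of scalars) of phase
#'   differences in (-pi, pi].
#' @param cert List of K non-negative arrays of certainties, same shapes.
#' @param dirs K x ndim matrix of unit direction vectors.
#' @param rho Center frequency of the bank (radians/voxel).
#' @return List with `field` (displacement array, trailing component
#'   dimension) and `certainty` (sum of the K certainties).
#' @export
phase_wls <- function(dphi, cert, dirs, rho) {
  K <- nrow(dirs)
  nd <- ncol(dirs)
  if (length(dphi) != K || length(cert) != K)
    stop("dphi and cert must have one entry per direction", call. = FALSE)
  shape <- dim(dphi[[1]])
  if (is.null(shape)) shape <- c(length(dphi[[1]]), 1L)
  zero <- array(0, shape)
  c2 <- lapply(cert, function(c) c^2)
  csum <- Reduce(`+`, cert)

  M <- vector("list", nd * nd)
  b <- vector("list", nd)
  ent <- function(i, j) (i - 1L) * nd + j
  for (i in seq_len(nd)) {
    b[[i]] <- zero
    for (j in i:nd) M[[ent(i, j)]] <- zero
  }
  for (k in seq_len(K)) {
    for (i in seq_len(nd)) {
      b[[i]] <- b[[i]] + c2[[k]] * dirs[k, i] * dphi[[k]]
      for (j in i:nd)
        M[[ent(i, j)]] <- M[[ent(i, j)]] + c2[[k]] * dirs[k, i] * dirs[k, j]
    }
  }

  if (nd == 2L) {
    er <- .sym_eig_range2(M[[ent(1, 1)]], M[[ent(1, 2)]], M[[ent(2, 2)]])
    det_ <- M[[ent(1, 1)]] * M[[ent(2, 2)]] - M[[ent(1, 2)]]^2
    ok <- er$min > 1e-9 * er$max & csum > 1e-12 * max(csum)
    det_safe <- ifelse(ok, det_, 1)
    d1 <- ifelse(ok, (M[[ent(2, 2)]] * b[[1]] - M[[ent(1, 2)]] * b[[2]]) / det_safe, 0)
    d2 <- ifelse(ok, (M[[ent(1, 1)]] * b[[2]] - M[[ent(1, 2)]] * b[[1]]) / det_safe, 0)
    comps <- list(d1, d2)
  } else {
    m11 <- M[[ent(1, 1)]]; m12 <- M[[ent(1, 2)]]; m13 <- M[[ent(1, 3)]]
    m22 <- M[[ent(2, 2)]]; m23 <- M[[ent(2, 3)]]; m33 <- M[[ent(3, 3)]]
    er <- .sym_eig_range3(m11, m12, m13, m22, m23, m33)
    ok <- er$min > 1e-9 * er$max & csum > 1e-12 * max(csum)
    det_ <- m11 * (m22 * m33 - m23^2) - m12 * (m12 * m33 - m23 * m13) +
            m13 * (m12 * m23 - m22 * m13)
    det_safe <- ifelse(ok, det_, 1)
    # adjugate (symmetric input -> symmetric inverse)
    a11 <- m22 * m33 - m23^2;  a12 <- m13 * m23 - m12 * m33
    a13 <- m12 * m23 - m13 * m22
    a22 <- m11 * m33 - m13^2;  a23 <- m12 * m13 - m11 * m23
    a33 <- m11 * m22 - m12^2
    d1 <- ifelse(ok, (a11 * b[[1]] + a12 * b[[2]] + a13 * b[[3]]) / det_safe, 0)
    d2 <- ifelse(ok, (a12 * b[[1]] + a22 * b[[2]] + a23 * b[[3]]) / det_safe, 0)
    d3 <- ifelse(ok, (a13 * b[[1]] + a23 * b[[2]] + a33 * b[[3]]) / det_safe, 0)
    comps <- list(d1, d2, d3)
  }
  field <- array(0, c(shape, nd))
  for (a in seq_len(nd))
    field <- .set_field_comp(field, a, array(comps[[a]] / rho, shape))
  list(field = field, certainty = array(csum, shape))
}

# Internal: Morphons update from precomputed fixed-image responses.
.morphons_update_resp <- function(rf, w, bank) {
  rw <- apply_bank(w, bank)
  dp <- local_dephasing(rf, rw)
  phase_wls(dp$dphi, dp$cert, bank$directions, bank$rho)
}

#' Morphons (local phase) update field
#'
#' One field-computation step of the Morphons method: filters both images
#' with the quadrature bank, measures the per-direction local dephasing and
#' certainty ([local_dephasing()]), and solves the per-voxel weighted
#' least-squares problem ([phase_wls()]) for the update displacement. The
#' returned certainty is the sum of the per-filter certainties. Because the
#' local phase ignores positive intensity scaling, `morphons_update(f, a*f)`
#' is zero (to floating-point precision) for any `a > 0`.
#'
#' @param f Fixed image.
#' @param w Moving image warped by the current accumulated field.
#' @param bank A [loglet_bank()] matching the image dimensionality.
#' @return List with `field` (update displacement, with the convention
#'   `f(x) ~ w(x + field(x))`) and `certainty`.
#' @export
morphons_update <- function(f, w, bank) {
  .check_image(f, "f")
  .check_image(w, "w")
  if (!identical(dim(f), dim(w)))
    stop("f and w must share a grid", call. = FALSE)
  .morphons_update_resp(apply_bank(f, bank), w, bank)
}

#' Demons (intensity difference) update field
#'
#' The classical SSD-driven per-voxel update used as the intensity-based
#' comparator: `d = (f - w) * grad(f) / (|grad(f)|^2 + (f - w)^2)`, zero
#' where the denominator vanishes. Unlike the phase-based update this reacts
#' to any intensity difference, including pure contrast changes. The
#' certainty is identically 1 (the method has no certainty concept).
#'
#' @inheritParams morphons_update
#' @return List with `field` and `certainty` (all ones).
#' @export
demons_update <- function(f, w) {
  .check_image(f, "f")
  .check_image(w, "w")
  if (!identical(dim(f), dim(w)))
    stop("f and w must share a grid", call. = FALSE)
  nd <- length(dim(f))
  diff <- f - w
  g <- lapply(seq_len(nd), function(a) .grad_axis(f, a))
  denom <- Reduce(`+`, lapply(g, function(x) x^2)) + diff^2
  eps <- 1e-12 * max(denom)
  ok <- denom > eps
  field <- array(0, c(dim(f), nd))
  for (a in seq_len(nd))
    field <- .set_field_comp(field, a,
      array(ifelse(ok, diff * g[[a]] / ifelse(ok, denom, 1), 0), dim(f)))
  list(field = field, certainty = array(1, dim(f)))
}

#' Accumulate certainty maps
#'
#' Combines the accumulated certainty `ca` with the update certainty `cu`
#' by the self-weighted rule `(ca^2 + cu^2) / (ca + cu)` (each certainty is
#' weighted by itself), returning 0 where both vanish. The result is
#' non-negative and never exceeds `max(ca, cu)`.
#'
#' @param ca,cu Non-negative arrays on the same grid.
#' @return Accumulated certainty array.
#' @export
accumulate_certainty <- function(ca, cu) {
  if (any(ca < 0) || any(cu < 0))
    stop("certainties must be non-negative", call. = FALSE)
  s <- ca + cu
  ifelse(s > 0, (ca^2 + cu^2) / ifelse(s > 0, s, 1), 0)
}

#' Accumulate a displacement field with an update field
#'
#' Combines the accumulated field `Da` with the update `Du`, damped by the
#' certainty weight `w = cu / (ca + cu)` (taken as 1 when no certainties are
#' given, and 0 where `ca + cu = 0`):
#' \describe{
#'   \item{`additive`}{`Da + w * Du` — plain damped addition. Fast but not
#'     consistent with composing the deformations, and can fold the grid.}
#'   \item{`compositive`}{`Da %oplus% (w * Du)` via [compose_fields()] — the
#'     accumulated deformation is the composition of the two.}
#'   \item{`diffeomorphic`}{`Da %oplus% (exp(w * Du) - Id)` via
#'     [exp_field()] — the damped update is exponentiated before composition,
#'     so each increment is itself a diffeomorphism and the accumulated
#'     deformation remains invertible.}
#' }
#'
#' @param Da Accumulated displacement field.
#' @param Du Update displacement field, same grid.
#' @param ca,cu Optional certainty arrays; both `NULL` means undamped
#'   accumulation (weight 1), as used for Demons.
#' @param mode One of `"additive"`, `"compositive"`, `"diffeomorphic"`.
#' @param max_step Scaling threshold passed to [exp_field()].
#' @return The accumulated field.
#' @export
accumulate_field <- function(Da, Du, ca = NULL, cu = NULL,
                             mode = c("diffeomorphic", "additive", "compositive"),
                             max_step = 0.5) {
  mode <- match.arg(mode)
  .check_field(Da, "Da")
  .check_field(Du, "Du")
  if (!identical(dim(Da), dim(Du)))
    stop("fields must share a grid", call. = FALSE)
  nd <- .field_ndim(Du)
  if (is.null(ca) != is.null(cu))
    stop("supply both certainties or neither", call. = FALSE)
  wDu <- Du
  if (!is.null(ca)) {
    if (any(ca < 0) || any(cu < 0))
      stop("certainties must be non-negative", call. = FALSE)
    s <- ca + cu
    wgt <- ifelse(s > 0, cu / ifelse(s > 0, s, 1), 0)
    for (a in seq_len(nd))
      wDu <- .set_field_comp(wDu, a, .field_comp(Du, a) * wgt)
  }
  switch(mode,
    additive      = Da + wDu,
    compositive   = compose_fields(Da, wDu),
    diffeomorphic = compose_fields(Da, exp_field(wDu, max_step)))
}

#' Normalized convolution of a scalar field
#'
#' Certainty-weighted Gaussian smoothing:
#' `s *_h g = ((h * s) conv g) / (h conv g)` with `g` a Gaussian kernel of
#' variance `sigma2` (truncated at 4 standard deviations, zero-padded). The
#' quotient is a weighted average, so the output sup-norm never exceeds the
#' input sup-norm, and values propagate from high-certainty voxels into
#' low-certainty regions. Where the denominator falls below `1e-12` of its
#' maximum the output is set to 0.
#'
#' @param s Scalar field (2D or 3D array).
#' @param h Non-negative certainty array, same shape.
#' @param sigma2 Gaussian variance in voxels^2 (default 2).
#' @return Smoothed array, same shape as `s`.
#' @export
normalized_convolution <- function(s, h, sigma2 = 2) {
  if (!identical(dim(s), dim(h)))
    stop("s and h must share a grid", call. = FALSE)
  if (any(h < 0))
    stop("certainty h must be non-negative", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("sigma2 must be a positive scalar", call. = FALSE)
  sd <- sqrt(sigma2)
  num <- .gauss_smooth(h * s, sd)
  den <- .gauss_smooth(h, sd)
  eps <- 1e-12 * max(den)
  ifelse(den > eps, num / ifelse(den > eps, den, 1), 0)
}

#' Certainty-weighted regularization of a displacement field
#'
#' Applies [normalized_convolution()] with normalization `ca` to every
#' component of the accumulated field, then to the certainty map itself, so
#' that displacement vectors and their confidence stay in correspondence.
#' Zero padding means certainty outside the volume is treated as zero, which
#' cancels any boundary-padding influence on the field.
#'
#' @param Da Accumulated displacement field.
#' @param ca Accumulated certainty array on the field's grid.
#' @param sigma2 Gaussian variance in voxels^2 (default 2).
#' @return List with regularized `field` and `certainty`.
#' @export
regularize_field <- function(Da, ca, sigma2 = 2) {
  .check_field(Da, "Da")
  nd <- .field_ndim(Da)
  out <- Da
  for (a in seq_len(nd))
    out <- .set_field_comp(out, a,
      normalized_convolution(.field_comp(Da, a), ca, sigma2))
  list(field = out, certainty = normalized_convolution(ca, ca, sigma2))
}
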