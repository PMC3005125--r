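# Synthetic phantoms: blurred-disk pairs for the contrast-invariance and
# missing-structure experiments, and textured pairs deformed by known
# diffeomorphisms for parameter-recovery tests. All generators are
# deterministic functions of their arguments (and seed).

# Squared distance from the image center, for a square/cubic grid.
.center_dist <- function(size, ndim) {
  c0 <- (size + 1) / 2
  idx <- .grid_coords(rep(size, ndim))
  d2 <- rowSums((idx - c0)^2)
  array(sqrt(d2), rep(size, ndim))
}

#' Blurred-disk pair differing only in intensity scale
#'
#' Two images of the same Gaussian-blurred disk, the moving one obtained by
#' multiplying the fixed one by `intensity_scale` (default 0.75). The shapes
#' are identical, so the only difference is contrast: a phase-based
#' registration should return an (essentially) zero field, while an
#' intensity-based one is driven to deform the rim.
#'
#' @param size Image side length in voxels (default 128). 2D only.
#' @param r1 Disk radius in voxels (default 30).
#' @param blur_sigma Gaussian blur standard deviation in voxels (default 2).
#' @param intensity_scale Multiplicative factor applied to the moving image
#'   (default 0.75). The scaling is a bit-exact elementwise multiplication.
#' @return List with `fixed`, `moving` (arrays in `[0, 1]` before scaling)
#'   and `contour` (n x 2 matrix of circle points for overlay).
#' @export
phantom_scaled_disks <- function(size = 128L, r1 = 30, blur_sigma = 2,
                                 intensity_scale = 0.75) {
  if (r1 <= 0 || r1 >= size / 2) stop("need 0 < r1 < size/2", call. = FALSE)
  d <- .center_dist(size, 2L)
  fixed <- .gauss_smooth(array(as.numeric(d <= r1), dim(d)), blur_sigma)
  theta <- seq(0, 2 * pi, length.out = 181L)
  contour <- cbind((size + 1) / 2 + r1 * cos(theta),
                   (size + 1) / 2 + r1 * sin(theta))
  list(fixed = fixed, moving = intensity_scale * fixed, contour = contour)
}

#' Disk pair with a missing central structure
#'
#' The fixed image is a blurred disk of radius `r1 + r2` with a bright
#' central spot of radius `r2`; the moving image is a blurred disk of radius
#' `r1` with the same foreground intensity as the fixed disk and no central
#' structure. Registering moving to fixed forces the central bright region
#' to collapse onto (nearly) a single point of the moving image: additive
#' field accumulation typically folds the grid there (negative Jacobians),
#' while diffeomorphic accumulation compresses it towards, but not past,
#' zero volume.
#'
#' @param size Image side length in voxels (default 128). 2D only.
#' @param r1 Radius of the moving disk (default 30); the fixed disk has
#'   radius `r1 + r2`.
#' @param r2 Radius of the central bright spot (default 10).
#' @param blur_sigma Gaussian blur standard deviation (default 2).
#' @return List with `fixed` and `moving` arrays (intensities in `[0, 1]`).
#' @export
phantom_hole_disks <- function(size = 128L, r1 = 30, r2 = 10, blur_sigma = 2) {
  if (r1 <= 0 || r2 <= 0 || r1 + r2 >= size / 2)
    stop("need r1, r2 > 0 and r1 + r2 < size/2", call. = FALSE)
  d <- .center_dist(size, 2L)
  fixed <- 0.5 * (d <= r1 + r2) + 0.5 * (d <= r2)
  moving <- 0.5 * (d <= r1)
  list(fixed = .gauss_smooth(array(fixed, dim(d)), blur_sigma),
       moving = .gauss_smooth(array(moving, dim(d)), blur_sigma))
}

# Smoothstep boundary taper: 1 in the interior, decaying to 0 over `margin`
# voxels at every face. A deformation of a bounded grid must map the grid
# into itself, so synthetic velocities vanish at the boundary.
.boundary_taper <- function(shape, margin) {
  nd <- length(shape)
  w <- array(1, shape)
  for (a in seq_len(nd)) {
    i <- seq_len(shape[a])
    t <- pmin(1, (i - 1) / margin, (shape[a] - i) / margin)
    t <- t * t * (3 - 2 * t)
    perm <- order(c(a, setdiff(seq_len(nd), a)))
    w <- w * aperm(array(t, shape[c(a, setdiff(seq_len(nd), a))]), perm)
  }
  w
}

# Smooth random velocity field: per-component Gaussian-smoothed white noise,
# tapered to zero at the volume boundary and rescaled so the maximum vector
# norm equals `amplitude`.
.random_velocity <- function(shape, amplitude, smoothness, seed) {
  nd <- length(shape)
  V <- .with_seed(seed, {
    out <- array(stats::rnorm(prod(shape) * nd), c(shape, nd))
    for (a in seq_len(nd))
      out <- .set_field_comp(out, a, .gauss_smooth(.field_comp(out, a), smoothness))
    out
  })
  taper <- .boundary_taper(shape, margin = 2 * smoothness)
  for (a in seq_len(nd))
    V <- .set_field_comp(V, a, .field_comp(V, a) * taper)
  mx <- .field_max_norm(V)
  if (mx > 0 && amplitude > 0) V <- V * (amplitude / mx) else V <- V * 0
  V
}

#' Random ground-truth diffeomorphism
#'
#' Generates a smooth random stationary velocity field (Gaussian-smoothed
#' white noise, tapered to zero over a `2 * smoothness`-voxel boundary
#' margin so the flow maps the grid into itself, rescaled to maximum vector
#' norm `amplitude`) and returns its
#' exponential ([exp_field()]), which is a diffeomorphism by construction;
#' the positive minimum Jacobian is asserted. The generating velocity is
#' attached as attribute `"velocity"` so that the exact inverse
#' `exp_field(-velocity)` is available.
#'
#' @param shape Grid shape (2 or 3 integers).
#' @param amplitude Maximum displacement norm of the velocity, in voxels.
#' @param smoothness Gaussian smoothing standard deviation of the noise, in
#'   voxels (default 6).
#' @param seed Integer seed; the same seed reproduces the same field.
#' @return Displacement field with attribute `"velocity"`.
#' @export
random_diffeo <- function(shape, amplitude, smoothness = 6, seed = 1L) {
  if (amplitude < 0) stop("amplitude must be non-negative", call. = FALSE)
  if (smoothness <= 0) stop("smoothness must be positive", call. = FALSE)
  V <- .random_velocity(as.integer(shape), amplitude, smoothness, seed)
  D <- exp_field(V)
  if (min(jacobian_determinant(D)) <= 0)
    stop("generated field is not diffeomorphic; increase smoothness", call. = FALSE)
  attr(D, "velocity") <- V
  D
}

#' Textured pair deformed by a known diffeomorphism
#'
#' The fixed image is a band-limited random texture (Gaussian-smoothed white
#' noise rescaled to `[0, 1]`) with an embedded smooth blob; the moving
#' image is the fixed image warped by a [random_diffeo()] of the requested
#' amplitude. Because warping by the forward field `exp(V)` means a
#' registration of (fixed, moving) should recover the inverse deformation,
#' the exact inverse `exp_field(-V)` is returned as `truth` — the field a
#' correct registration reproduces — alongside the applied field `deform`.
#' Optionally the moving image's blob region is multiplied by
#' `contrast_scale` to emulate a local contrast-enhancement difference.
#'
#' @param size Image side length in voxels (default 256). 2D only.
#' @param amplitude Maximum displacement of the applied deformation, in
#'   voxels (default 4).
#' @param smoothness Smoothness of the deforming velocity field in voxels
#'   (default 24, organ-scale motion well inside the validity regime of the
#'   scaling-and-squaring exponential).
#' @param texture_sigma Smoothing of the texture noise in voxels (default
#'   1.5, a CT-like point spread; the texture must survive one resampling
#'   without aliasing for the warped pair to be matchable).
#' @param seed Integer seed.
#' @param contrast_scale Optional multiplicative intensity factor applied to
#'   the moving image inside the blob region (default `NULL`: none).
#' @return List with `fixed`, `moving`, `deform` (the applied field),
#'   `truth` (its exact inverse, the registration target) and `blob`
#'   (the blob weight map in `[0, 1]`).
#' @export
phantom_textured <- function(size = 256L, amplitude = 4, smoothness = 24,
                             texture_sigma = 1.5, seed = 1L,
                             contrast_scale = NULL) {
  shape <- rep(as.integer(size), 2L)
  tex <- .with_seed(seed + 1L,
    .gauss_smooth(array(stats::rnorm(prod(shape)), shape), texture_sigma))
  tex <- (tex - min(tex)) / (max(tex) - min(tex))
  blob <- exp(-(.center_dist(size, 2L) / (size / 6))^2)
  fixed <- 0.7 * tex + 0.3 * blob
  if (amplitude > 0) {
    deform <- random_diffeo(shape, amplitude, smoothness, seed)
    truth <- exp_field(-attr(deform, "velocity"))
  } else {
    deform <- .zero_field(shape)
    truth <- deform
  }
  moving <- warp_volume(fixed, deform)
  if (!is.null(contrast_scale))
    moving <- moving * (1 + (contrast_scale - 1) * blob)
  list(fixed = fixed, moving = moving, deform = deform, truth = truth,
       blob = blob)
}
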