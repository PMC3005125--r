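#' Warp a volume by a displacement field
#'
#' Resamples the moving image `m` at the deformed positions
#' `x + D(x)`, i.e. computes `(m %diamond% D)(x) = m(x + D(x))`.
#' The field `D` lives on the target (fixed) grid, with components in voxel
#' units. Sample coordinates falling outside the grid of `m` are clamped to
#' the nearest in-grid point, so the warped image never extrapolates.
#'
#' @param m Moving image: 2D or 3D numeric array.
#' @param D Displacement field: numeric array of dimension `c(dim(m), ndim)`.
#' @param interpolation `"linear"` (default) for scalar images, `"nearest"`
#'   for label masks.
#' @return A numeric array of the same shape as `m`.
#' @examples
#' m <- matrix(runif(64), 8, 8)
#' D <- array(0, c(8, 8, 2))
#' stopifnot(identical(warp_volume(m, D), m))
#' @export
warp_volume <- function(m, D, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  .check_image(m, "m")
  .check_field(D, "D")
  if (!identical(dim(m), as.integer(.field_shape(D))) &&
      !identical(as.integer(dim(m)), as.integer(.field_shape(D))))
    stop("field grid does not match the image grid", call. = FALSE)
  shape <- dim(m)
  nd <- length(shape)
  coords <- .grid_coords(shape)
  mode(coords) <- "double"
  for (a in seq_len(nd))
    coords[, a] <- coords[, a] + as.vector(.field_comp(D, a))
  v <- if (interpolation == "linear") .interp_linear(m, coords)
       else .interp_nearest(m, coords)
  array(v, shape)
}

#' Warp a displacement field by another field
#'
#' Resamples every component of `D1` at the deformed positions
#' `x + D2(x)`: the field analogue of [warp_volume()], written
#' `D1 %diamond% D2 = D1 o (Id + D2)`. Both fields must share a grid.
#'
#' @param D1,D2 Displacement fields on the same grid.
#' @return The resampled field, same shape as `D1`.
#' @export
warp_field <- function(D1, D2) {
  .check_field(D1, "D1")
  .check_field(D2, "D2")
  if (!identical(dim(D1), dim(D2)))
    stop("fields must share a grid", call. = FALSE)
  shape <- .field_shape(D1)
  nd <- length(shape)
  coords <- .grid_coords(shape)
  mode(coords) <- "double"
  for (a in seq_len(nd))
    coords[, a] <- coords[, a] + as.vector(.field_comp(D2, a))
  out <- D1
  for (a in seq_len(nd))
    out <- .set_field_comp(out, a, array(.interp_linear(.field_comp(D1, a), coords), shape))
  out
}

#' Compositive accumulation of displacement fields
#'
#' Combines two displacement fields so that the resulting deformation is the
#' composition of the individual deformations:
#' `compose_fields(D1, D2) = D2 + warp_field(D1, D2)`, whose associated
#' deformation is `(Id + D1) o (Id + D2)`. Unlike plain addition, this keeps
#' iterated accumulation consistent with successive warping.
#'
#' @param D1,D2 Displacement fields on the same grid. `D2` is applied first.
#' @return The accumulated field `D1 %oplus% D2`.
#' @export
compose_fields <- function(D1, D2) {
  D2 + warp_field(D1, D2)
}

#' Exponential of a velocity field by scaling and squaring
#'
#' Computes the displacement field `E` of the group exponential of a
#' stationary velocity field `D`: `Id + E ~ exp(D)`, the time-1 flow of the
#' autonomous ODE `du/dt = D(u)`. `D` is first divided by `2^k`, with `k` the
#' smallest non-negative integer such that the scaled field's maximum vector
#' norm is below `max_step` voxels; a first-order step approximates the flow
#' at time `2^-k`, and `k` recursive self-compositions (squarings) via
#' [compose_fields()] recover the flow at time 1. For differentiable `D` the
#' result is a diffeomorphism: its Jacobian determinant stays positive and
#' `exp_field(-D)` is its inverse. With `k = 0` (already-small fields) the
#' scheme reduces to the first-order approximation `E = D`.
#'
#' @param D Velocity field (voxel units).
#' @param max_step Scaling threshold in voxels (default 0.5): the scaled
#'   field used for the first-order step is strictly smaller than this.
#' @return Displacement field of the exponentiated deformation.
#' @export
exp_field <- function(D, max_step = 0.5) {
  .check_field(D, "D")
  if (!is.numeric(max_step) || length(max_step) != 1L || max_step <= 0)
    stop("max_step must be a positive scalar", call. = FALSE)
  mx <- .field_max_norm(D)
  k <- 0L
  while (mx / 2^k >= max_step && k < 60L) k <- k + 1L
  E <- D / 2^k
  for (i in seq_len(k)) E <- compose_fields(E, E)
  E
}

#' Jacobian determinant map of a deformation
#'
#' Per-voxel determinant of the Jacobian of the deformation `Id + D`,
#' `J_ij = delta_ij + d d_i / d x_j`, using centered finite differences in
#' the interior and one-sided differences at boundary voxels. The value is
#' the local volume ratio of the deformation: 1 means no volume change,
#' values in (0, 1) compression, values above 1 expansion, and negative
#' values a folded ("inverted") voxel, which no physical deformation can
#' produce.
#'
#' @param D Displacement field.
#' @return Numeric array of determinants on the field's grid.
#' @export
jacobian_determinant <- function(D) {
  .check_field(D, "D")
  shape <- .field_shape(D)
  nd <- length(shape)
  if (any(shape < 3L))
    stop("grid must have at least 3 voxels per axis", call. = FALSE)
  g <- vector("list", nd)
  for (i in seq_len(nd)) {
    g[[i]] <- vector("list", nd)
    di <- .field_comp(D, i)
    for (j in seq_len(nd)) {
      g[[i]][[j]] <- .grad_axis(di, j)
      if (i == j) g[[i]][[j]] <- g[[i]][[j]] + 1
    }
  }
  if (nd == 2L) {
    g[[1]][[1]] * g[[2]][[2]] - g[[1]][[2]] * g[[2]][[1]]
  } else {
    g[[1]][[1]] * (g[[2]][[2]] * g[[3]][[3]] - g[[2]][[3]] * g[[3]][[2]]) -
    g[[1]][[2]] * (g[[2]][[1]] * g[[3]][[3]] - g[[2]][[3]] * g[[3]][[1]]) +
    g[[1]][[3]] * (g[[2]][[1]] * g[[3]][[2]] - g[[2]][[2]] * g[[3]][[1]])
  }
}
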