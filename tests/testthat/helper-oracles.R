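# Independent oracles and small generators shared across the test files.
# Oracles are deliberately written as plain per-point loops or explicit
# integrators, separate from the vectorized implementation paths they check.

# Explicit Euler integration of the flow ODE du/dt = D(u), u(0) = x, over
# `steps` uniform time steps, with the same clamped linear interpolation
# contract as the package. Integrates from every `stride`-th grid point and
# returns the time-1 displacements u(1) - x as an n x 2 matrix together with
# the starting indices.
euler_flow_2d <- function(V, steps = 4096L, stride = 1L) {
  shape <- dim(V)[1:2]
  n1 <- shape[1]; n2 <- shape[2]
  V1 <- V[, , 1]; V2 <- V[, , 2]
  u0 <- morphons:::.grid_coords(shape)
  keep <- (u0[, 1] - 1L) %% stride == 0L & (u0[, 2] - 1L) %% stride == 0L
  u0 <- u0[keep, , drop = FALSE]
  x <- as.numeric(u0[, 1]); y <- as.numeric(u0[, 2])
  h <- 1 / steps
  for (s in seq_len(steps)) {
    xc <- pmin(pmax(x, 1), n1)
    yc <- pmin(pmax(y, 1), n2)
    i0 <- pmin(floor(xc), n1 - 1); j0 <- pmin(floor(yc), n2 - 1)
    fx <- xc - i0; fy <- yc - j0
    k00 <- i0 + n1 * (j0 - 1)
    w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
    w01 <- (1 - fx) * fy;       w11 <- fx * fy
    x <- x + h * (w00 * V1[k00] + w10 * V1[k00 + 1] +
                  w01 * V1[k00 + n1] + w11 * V1[k00 + n1 + 1])
    y <- y + h * (w00 * V2[k00] + w10 * V2[k00 + 1] +
                  w01 * V2[k00 + n1] + w11 * V2[k00 + n1 + 1])
  }
  list(disp = cbind(x - u0[, 1], y - u0[, 2]), start = u0)
}

# Sup-norm difference between a displacement field and an Euler-integrated
# flow at the integration start points.
euler_sup_diff <- function(D, flow) {
  idx1 <- cbind(flow$start, 1L)
  idx2 <- cbind(flow$start, 2L)
  max(sqrt((D[idx1] - flow$disp[, 1])^2 + (D[idx2] - flow$disp[, 2])^2))
}

# Scalar per-point linear interpolation with boundary clamping (2D), the
# brute-force counterpart of the vectorized resampler.
interp_point_2d <- function(arr, x, y) {
  n1 <- nrow(arr); n2 <- ncol(arr)
  x <- min(max(x, 1), n1); y <- min(max(y, 1), n2)
  i0 <- min(floor(x), n1 - 1); j0 <- min(floor(y), n2 - 1)
  fx <- x - i0; fy <- y - j0
  (1 - fx) * (1 - fy) * arr[i0, j0] + fx * (1 - fy) * arr[i0 + 1, j0] +
    (1 - fx) * fy * arr[i0, j0 + 1] + fx * fy * arr[i0 + 1, j0 + 1]
}

# Per-voxel loop warp oracle (2D).
warp_oracle_2d <- function(m, D) {
  out <- m
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- interp_point_2d(m, i + D[i, j, 1], j + D[i, j, 2])
  out
}

# Maximum per-voxel vector norm of a field.
field_sup <- function(D) morphons:::.field_max_norm(D)

# Smooth random test field with given sup-norm (wraps the package's
# generator used by random_diffeo).
smooth_field <- function(shape, amplitude, smoothness, seed) {
  morphons:::.random_velocity(as.integer(shape), amplitude, smoothness, seed)
}

# Brute-force grid minimizer of the certainty-weighted phase energy
# sum_k (c_k (rho eta_k' d - dphi_k))^2: a coarse cartesian sweep followed
# by a fine sweep around the coarse minimum. Returns the best grid point.
wls_grid_oracle <- function(dphi, cert, dirs, rho, span = 2, step = 0.05,
                            refine = step / 10) {
  nd <- ncol(dirs)
  best_on <- function(center, half, by) {
    g <- lapply(seq_len(nd), function(a)
      seq(center[a] - half, center[a] + half, by = by))
    cand <- as.matrix(expand.grid(g))
    energy <- numeric(nrow(cand))
    for (k in seq_len(nrow(dirs))) {
      proj <- cand %*% dirs[k, ]
      energy <- energy + (cert[k] * (rho * proj - dphi[k]))^2
    }
    cand[which.min(energy), ]
  }
  coarse <- best_on(rep(0, nd), span, step)
  best_on(coarse, 1.5 * step, refine)
}

# Centered/one-sided finite-difference Jacobian determinant via a per-voxel
# loop (2D).
jacobian_oracle_2d <- function(D) {
  n1 <- dim(D)[1]; n2 <- dim(D)[2]
  gr <- function(comp, i, j, axis) {
    if (axis == 1) {
      if (i == 1) comp[2, j] - comp[1, j]
      else if (i == n1) comp[n1, j] - comp[n1 - 1, j]
      else (comp[i + 1, j] - comp[i - 1, j]) / 2
    } else {
      if (j == 1) comp[i, 2] - comp[i, 1]
      else if (j == n2) comp[i, n2] - comp[i, n2 - 1]
      else (comp[i, j + 1] - comp[i, j - 1]) / 2
    }
  }
  out <- matrix(0, n1, n2)
  d1 <- D[, , 1]; d2 <- D[, , 2]
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    j11 <- 1 + gr(d1, i, j, 1); j12 <- gr(d1, i, j, 2)
    j21 <- gr(d2, i, j, 1);     j22 <- 1 + gr(d2, i, j, 2)
    out[i, j] <- j11 * j22 - j12 * j21
  }
  out
}
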