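# Low-level array utilities: interpolation, shifts, convolution, gradients.
# Images are plain numeric arrays (2D or 3D); displacement fields are numeric
# arrays with one trailing component dimension, in voxel units of the grid
# they are defined on.

.check_image <- function(x, name = "image") {
  if (!is.array(x) || !(length(dim(x)) %in% c(2L, 3L)))
    stop(name, " must be a 2D or 3D numeric array", call. = FALSE)
  if (!all(is.finite(x)))
    stop(name, " contains non-finite values", call. = FALSE)
  invisible(x)
}

.check_field <- function(D, name = "field") {
  d <- dim(D)
  if (!is.array(D) || !(length(d) %in% c(3L, 4L)) || d[length(d)] != length(d) - 1L)
    stop(name, " must be an array with a trailing component dimension ",
         "matching the grid dimensionality", call. = FALSE)
  if (!all(is.finite(D)))
    stop(name, " contains non-finite values", call. = FALSE)
  invisible(D)
}

.field_shape <- function(D) {
  d <- dim(D)
  d[-length(d)]
}

.field_ndim <- function(D) length(dim(D)) - 1L

.field_comp <- function(D, a) {
  d <- dim(D)
  nd <- length(d) - 1L
  if (nd == 2L) D[, , a] else D[, , , a]
}

.set_field_comp <- function(D, a, value) {
  nd <- length(dim(D)) - 1L
  if (nd == 2L) D[, , a] <- value else D[, , , a] <- value
  D
}

.zero_field <- function(shape) {
  array(0, dim = c(shape, length(shape)))
}

#' @keywords internal
#' @noRd
.field_max_norm <- function(D) {
  nd <- .field_ndim(D)
  s <- .field_comp(D, 1L)^2
  for (a in seq_len(nd)[-1L]) s <- s + .field_comp(D, a)^2
  sqrt(max(s))
}

# Voxel index coordinates of a grid, as an n x d integer matrix.
.grid_coords <- function(shape) {
  arrayInd(seq_len(prod(shape)), .dim = shape)
}

# Multilinear interpolation of `arr` at 1-based positions `coords`
# (n x d matrix). Out-of-grid positions are clamped to the boundary.
.interp_linear <- function(arr, coords) {
  dm <- dim(arr)
  d <- length(dm)
  if (any(dm < 2L)) stop("grid must have at least 2 voxels per axis", call. = FALSE)
  i0 <- vector("list", d)
  fr <- vector("list", d)
  for (a in seq_len(d)) {
    x <- pmin(pmax(coords[, a], 1), dm[a])
    lo <- pmin(floor(x), dm[a] - 1)
    i0[[a]] <- as.integer(lo)
    fr[[a]] <- x - lo
  }
  out <- 0
  for (corner in 0:(2^d - 1L)) {
    bits <- bitwAnd(corner, 2L^(seq_len(d) - 1L)) > 0L
    w <- 1
    idx <- matrix(0L, nrow(coords), d)
    for (a in seq_len(d)) {
      if (bits[a]) {
        w <- w * fr[[a]]
        idx[, a] <- i0[[a]] + 1L
      } else {
        w <- w * (1 - fr[[a]])
        idx[, a] <- i0[[a]]
      }
    }
    out <- out + w * arr[idx]
  }
  out
}

# Nearest-neighbour interpolation with the same clamping contract.
.interp_nearest <- function(arr, coords) {
  dm <- dim(arr)
  d <- length(dm)
  idx <- matrix(0L, nrow(coords), d)
  for (a in seq_len(d))
    idx[, a] <- as.integer(round(pmin(pmax(coords[, a], 1), dm[a])))
  arr[idx]
}

# Zero-pad `arr` by `r` voxels per side per axis (r: length-d integer).
.pad_zero <- function(arr, r) {
  dm <- dim(arr)
  d <- length(dm)
  pad <- array(0, dm + 2L * r)
  idx <- lapply(seq_len(d), function(a) (r[a] + 1L):(r[a] + dm[a]))
  do.call(`[<-`, c(list(pad), idx, list(value = arr)))
}

# Full nD convolution with a real kernel of odd extent, zero-padding outside
# the array: out(x) = sum_u kern(u) * arr(x - u), u in [-r, r]^d.
.conv_nd <- function(arr, kern) {
  dk <- dim(kern)
  if (any(dk %% 2L == 0L)) stop("kernel extent must be odd", call. = FALSE)
  r <- (dk - 1L) %/% 2L
  dm <- dim(arr)
  d <- length(dm)
  pad <- .pad_zero(arr, r)
  out <- array(0, dm)
  taps <- which(kern != 0)
  tidx <- arrayInd(taps, .dim = dk)
  for (t in seq_along(taps)) {
    u <- tidx[t, ] - r - 1L
    win <- lapply(seq_len(d), function(a) (r[a] + 1L - u[a]):(r[a] + dm[a] - u[a]))
    out <- out + kern[taps[t]] * do.call(`[`, c(list(pad), win, list(drop = FALSE)))
  }
  out
}

# 1D convolution of an nD array along one axis (zero-padded).
.conv1_axis <- function(arr, k1d, axis) {
  dm <- dim(arr)
  d <- length(dm)
  perm <- c(axis, setdiff(seq_len(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  n <- da[1L]
  m <- matrix(a, nrow = n)
  r <- (length(k1d) - 1L) %/% 2L
  zpad <- matrix(0, r, ncol(m))
  padm <- rbind(zpad, m, zpad)
  out <- matrix(0, n, ncol(m))
  for (u in -r:r)
    out <- out + k1d[u + r + 1L] * padm[(r + 1L - u):(r + n - u), , drop = FALSE]
  dim(out) <- da
  aperm(out, order(perm))
}

# Normalized 1D Gaussian tap vector, truncated at `trunc` standard deviations.
.gauss_kernel1d <- function(sd, trunc = 4) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  r <- max(1L, as.integer(ceiling(trunc * sd)))
  k <- exp(-((-r:r)^2) / (2 * sd^2))
  k / sum(k)
}

# Separable Gaussian smoothing with zero padding; `renormalized = TRUE`
# divides by the smoothed indicator so that constants are preserved up to
# the boundary (used for pyramid antialiasing).
.gauss_smooth <- function(arr, sd, trunc = 4, renormalized = FALSE) {
  k <- .gauss_kernel1d(sd, trunc)
  out <- arr
  for (a in seq_along(dim(arr))) out <- .conv1_axis(out, k, a)
  if (renormalized) {
    ones <- array(1, dim(arr))
    for (a in seq_along(dim(arr))) ones <- .conv1_axis(ones, k, a)
    out <- out / ones
  }
  out
}

# Per-axis first derivative: centered differences in the interior, one-sided
# first differences at boundary voxels.
.grad_axis <- function(arr, axis) {
  dm <- dim(arr)
  d <- length(dm)
  perm <- c(axis, setdiff(seq_len(d), axis))
  a <- aperm(arr, perm)
  da <- dim(a)
  n <- da[1L]
  if (n < 2L) stop("grid too small for finite differences", call. = FALSE)
  m <- matrix(a, nrow = n)
  g <- matrix(0, n, ncol(m))
  if (n >= 3L)
    g[2:(n - 1L), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2L), , drop = FALSE]) / 2
  g[1L, ] <- m[2L, ] - m[1L, ]
  g[n, ] <- m[n, ] - m[n - 1L, ]
  dim(g) <- da
  aperm(g, order(perm))
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  }
  set.seed(seed)
  expr
}
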