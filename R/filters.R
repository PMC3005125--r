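# Quadrature (loglet) filter bank: directional complex bandpass filters with
# half-space frequency support. The response amplitude measures local signal
# energy in a direction; the response argument is the local phase, which is
# invariant to positive intensity scaling of the image.

# Radial log-normal profile: R(rho) = 1, R(rho/2) = R(2*rho) = 1/2.
.loglet_radial <- function(r, rho) {
  out <- numeric(length(r))
  pos <- r > 0
  out[pos] <- exp(-log(r[pos] / rho)^2 / log(2))
  out
}

# Non-antipodal vertex directions of a regular icosahedron: normalized cyclic
# permutations of (0, 1, phi) with phi the golden ratio. Evenly covers the
# half-sphere with 6 directions.
.icosahedron_directions <- function() {
  phi <- (1 + sqrt(5)) / 2
  d <- rbind(
    c(0,  1,  phi), c(0, -1,  phi),
    c(1,  phi, 0),  c(-1,  phi, 0),
    c(phi, 0,  1),  c(phi, 0, -1))
  d / sqrt(rowSums(d^2))
}

# Signed DFT frequencies in radians per voxel for an n-sample axis.
.dft_freq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  2 * pi * k / n
}

#' Build a loglet quadrature filter bank
#'
#' Constructs the K directional complex quadrature filters used for local
#' phase estimation: K = 4 in 2D (directions at angles `k*pi/4`, k = 0..3)
#' and K = 6 in 3D (the non-antipodal vertex directions of a regular
#' icosahedron). Each filter is defined in the frequency domain by the polar
#' separable function `H(w) = chi+(eta'w) * (eta' w/|w|)^2 * R(|w|)` with
#' `chi+` the positive half-space indicator and
#' `R(r) = exp(-ln^2(r/rho)/ln 2)` a log-normal radial bandpass centered on
#' `rho`. Spatial kernels are synthesized by sampling `H` on a DFT grid
#' (`synth_size` per axis), inverse transforming, centering, truncating to
#' `kernel_size` per axis, and removing any residual DC component from the
#' real part.
#'
#' @param rho Center frequency in radians/voxel, in (0, pi). Default `pi/2`,
#'   a wavelength of 4 voxels.
#' @param ndim 2 or 3.
#' @param kernel_size Odd spatial extent of the truncated kernels (default 9).
#' @param synth_size DFT grid used for kernel synthesis (default 64 in 2D,
#'   32 in 3D).
#' @return An object of class `loglet_bank`: list with `directions` (K x ndim
#'   matrix of unit vectors), `rho`, `kernel_size`, and `kernels` (list of K
#'   complex arrays).
#' @export
loglet_bank <- function(rho = pi / 2, ndim = 2, kernel_size = 9,
                        synth_size = if (ndim == 2) 64L else 32L) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= pi)
    stop("rho must lie in (0, pi)", call. = FALSE)
  if (!(ndim %in% c(2L, 3L)))
    stop("ndim must be 2 or 3", call. = FALSE)
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L || kernel_size < 5L)
    stop("kernel_size must be odd and >= 5", call. = FALSE)
  if (synth_size < 2L * kernel_size)
    stop("synth_size must be at least twice kernel_size", call. = FALSE)

  dirs <- if (ndim == 2L) {
    ang <- (0:3) * pi / 4
    cbind(cos(ang), sin(ang))
  } else {
    .icosahedron_directions()
  }

  n <- as.integer(synth_size)
  w <- .dft_freq(n)
  shape <- rep(n, ndim)
  wax <- vector("list", ndim)
  for (a in seq_len(ndim)) {
    base <- array(w, dim = shape)  # varies along axis 1
    wax[[a]] <- if (a == 1L) base else
      aperm(base, order(c(a, setdiff(seq_len(ndim), a))))
  }
  wnorm <- sqrt(Reduce(`+`, lapply(wax, function(x) x^2)))
  radial <- array(.loglet_radial(as.vector(wnorm), rho), dim = shape)

  r <- (kernel_size - 1L) %/% 2L
  cidx <- c((n - r + 1L):n, 1L:(r + 1L))
  kernels <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    dot <- Reduce(`+`, lapply(seq_len(ndim), function(a) dirs[k, a] * wax[[a]]))
    H <- array(0, shape)
    sup <- dot > 0
    H[sup] <- (dot[sup] / wnorm[sup])^2 * radial[sup]
    h <- fft(H, inverse = TRUE) / length(H)
    kern <- if (ndim == 2L) h[cidx, cidx] else h[cidx, cidx, cidx]
    re <- Re(kern)
    re <- re - mean(re)
    kernels[[k]] <- array(complex(real = re, imaginary = Im(kern)),
                          dim = rep(kernel_size, ndim))
  }
  structure(list(directions = dirs, rho = rho, kernel_size = kernel_size,
                 kernels = kernels),
            class = "loglet_bank")
}

#' @export
print.loglet_bank <- function(x, ...) {
  cat(sprintf("Loglet quadrature bank: %d directions in %dD, rho = %.4f rad/voxel, %d^%d kernels\n",
              nrow(x$directions), ncol(x$directions), x$rho,
              x$kernel_size, ncol(x$directions)))
  invisible(x)
}

#' Apply a quadrature filter bank to a volume
#'
#' Convolves the image with every complex kernel of the bank using spatial
#' convolution with zero padding outside the boundaries. The modulus of each
#' response is the local directional amplitude (signal energy, used as a
#' certainty weight); its argument is the local phase.
#'
#' @param v 2D or 3D numeric array.
#' @param bank A [loglet_bank()].
#' @return An object of class `quadrature_responses`: list with `q` (list of
#'   K complex response arrays) and the generating `bank`.
#' @export
apply_bank <- function(v, bank) {
  .check_image(v, "v")
  if (!inherits(bank, "loglet_bank")) stop("bank must be a loglet_bank", call. = FALSE)
  nd <- length(dim(v))
  if (nd != ncol(bank$directions))
    stop("image dimensionality does not match the bank", call. = FALSE)
  q <- lapply(bank$kernels, function(kern) {
    re <- .conv_nd(v, Re(kern))
    im <- .conv_nd(v, Im(kern))
    array(complex(real = re, imaginary = im), dim = dim(v))
  })
  structure(list(q = q, bank = bank), class = "quadrature_responses")
}

#' Local dephasing between two filtered images
#'
#' For each filter direction, computes the local phase difference
#' `dphi_k(x) = arg(q_f(x;k) * Conj(q_w(x;k)))` in (-pi, pi] and the
#' associated per-filter certainty `c_k(x) = A_f(x;k) * A_w(x;k)` (product of
#' response amplitudes). The phase difference is invariant to positive
#' multiplicative intensity scaling of either image, which is what makes
#' phase-driven registration robust to contrast differences.
#'
#' @param rf,rw [apply_bank()] responses of the fixed and the (warped)
#'   moving image, from the same bank and grid.
#' @return An object of class `dephasing`: list with `dphi` and `cert`
#'   (lists of K numeric arrays) and the `bank`.
#' @export
local_dephasing <- function(rf, rw) {
  if (!inherits(rf, "quadrature_responses") || !inherits(rw, "quadrature_responses"))
    stop("inputs must be quadrature_responses", call. = FALSE)
  if (length(rf$q) != length(rw$q) || !identical(dim(rf$q[[1]]), dim(rw$q[[1]])))
    stop("responses must come from the same bank and grid", call. = FALSE)
  K <- length(rf$q)
  dphi <- vector("list", K)
  cert <- vector("list", K)
  for (k in seq_len(K)) {
    prod_ <- rf$q[[k]] * Conj(rw$q[[k]])
    dphi[[k]] <- Arg(prod_)
    cert[[k]] <- Mod(rf$q[[k]]) * Mod(rw$q[[k]])
  }
  structure(list(dphi = dphi, cert = cert, bank = rf$bank), class = "dephasing")
}
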