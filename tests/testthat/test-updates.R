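test_that("morphons update is contrast-invariant and zero on identical images", {
  b <- loglet_bank()
  p <- phantom_scaled_disks(size = 64, r1 = 16)
  u0 <- morphons_update(p$fixed, p$fixed, b)
  expect_lt(max(abs(u0$field)), 1e-9)
  # certainty on identical images is the summed squared amplitudes
  rf <- apply_bank(p$fixed, b)
  expect_equal(u0$certainty, Reduce(`+`, lapply(rf$q, function(q) Mod(q)^2)),
               tolerance = 1e-12)
  for (alpha in c(0.75, 2)) {
    u <- morphons_update(p$fixed, alpha * p$fixed, b)
    expect_lt(max(abs(u$field)), 1e-6)
    expect_gt(max(u$certainty), 0)
  }
})

test_that("per-voxel WLS solve matches the brute-force energy minimizer", {
  set.seed(41)
  rho <- pi / 2
  worst <- 0
  for (i in 1:250) {
    # well-separated directions: jittered 2D bank angles
    ang <- (0:3) * pi / 4 + runif(4, -0.3, 0.3)
    dirs <- cbind(cos(ang), sin(ang))
    cert <- runif(4, 0.2, 1)
    dphi <- runif(4, -1, 1)
    sol <- phase_wls(lapply(dphi, function(v) array(v, c(1, 1))),
                     lapply(cert, function(v) array(v, c(1, 1))),
                     dirs, rho)
    d <- c(sol$field[1, 1, 1], sol$field[1, 1, 2])
    dg <- wls_grid_oracle(dphi, cert, dirs, rho)
    worst <- max(worst, max(abs(d - dg)))
    # optimality: the solver's energy never exceeds the best grid point's
    e <- function(dd) sum((cert * (rho * c(dirs %*% dd) - dphi))^2)
    expect_lte(e(d), e(dg) + 1e-9)
  }
  expect_lt(worst, 0.02)  # refined grid resolution times valley anisotropy
})

test_that("WLS solve falls back to zero for singular normal matrices", {
  rho <- pi / 2
  # all certainties zero
  sol <- phase_wls(lapply(1:4, function(k) array(0.5, c(1, 1))),
                   lapply(1:4, function(k) array(0, c(1, 1))),
                   loglet_bank()$directions, rho)
  expect_equal(sol$field[1, 1, ], c(0, 0))
  # one informative direction only: the normal matrix is rank one
  cert <- c(1, 0, 0, 0)
  sol1 <- phase_wls(lapply(c(0.8, 0, 0, 0), function(v) array(v, c(1, 1))),
                    lapply(cert, function(v) array(v, c(1, 1))),
                    loglet_bank()$directions, rho)
  expect_equal(sol1$field[1, 1, ], c(0, 0))
})

test_that("3D WLS solve minimizes the energy on icosahedral directions", {
  set.seed(17)
  dirs <- loglet_bank(ndim = 3)$directions
  rho <- pi / 2
  for (i in 1:20) {
    cert <- runif(6, 0.2, 1)
    dphi <- runif(6, -1, 1)
    sol <- phase_wls(lapply(dphi, function(v) array(v, c(1, 1, 1))),
                     lapply(cert, function(v) array(v, c(1, 1, 1))),
                     dirs, rho)
    d <- sol$field[1, 1, 1, ]
    e <- function(dd) sum((cert * (rho * c(dirs %*% dd) - dphi))^2)
    dg <- wls_grid_oracle(dphi, cert, dirs, rho, span = 1.5, step = 0.1)
    expect_lte(e(d), e(dg) + 1e-9)
    expect_lt(max(abs(d - dg)), 0.05)
  }
})

test_that("demons update is zero on identical images and recovers ramp shifts", {
  f <- matrix(rep(1:32, 32), 32, 32)
  u0 <- demons_update(f, f)
  expect_equal(max(abs(u0$field)), 0)
  expect_equal(u0$certainty, array(1, c(32, 32)))
  # w = f shifted by t: the classical update gives t/(1 + t^2) on a unit ramp
  t <- 0.3
  D <- array(0, c(32, 32, 2)); D[, , 1] <- -t
  w <- warp_volume(f, D)
  u <- demons_update(f, w)
  expect_equal(median(u$field[5:28, 5:28, 1]), t / (1 + t^2), tolerance = 1e-6)
})

test_that("demons update reacts to pure contrast change, unlike morphons", {
  p <- phantom_scaled_disks(size = 64, r1 = 16)
  ud <- demons_update(p$fixed, p$moving)
  um <- morphons_update(p$fixed, p$moving, loglet_bank())
  expect_gt(max(abs(ud$field)), 0.1)
  expect_lt(max(abs(um$field)), 1e-6)
})

test_that("certainty accumulation follows its closed form and bounds", {
  ca <- matrix(3, 4, 4); cu <- matrix(1, 4, 4)
  expect_equal(accumulate_certainty(ca, cu), matrix(2.5, 4, 4))
  c <- matrix(runif(16), 4, 4)
  expect_equal(accumulate_certainty(c, c), c)
  expect_equal(accumulate_certainty(matrix(0, 4, 4), c), c)
  # output between 0 and max(ca, cu)
  set.seed(2)
  for (i in 1:20) {
    a <- matrix(runif(16, 0, 5), 4, 4); u <- matrix(runif(16, 0, 5), 4, 4)
    out <- accumulate_certainty(a, u)
    expect_true(all(out >= 0))
    expect_true(all(out <= pmax(a, u) + 1e-12))
  }
  expect_error(accumulate_certainty(-ca, cu), "non-negative")
})

test_that("field accumulation respects neutral updates and damping limits", {
  Da <- smooth_field(c(16, 16), 2, 3, 6)
  Z <- array(0, c(16, 16, 2))
  one <- matrix(1, 16, 16)
  for (md in c("additive", "compositive", "diffeomorphic")) {
    expect_equal(accumulate_field(Da, Z, one, one, mode = md), Da,
                 tolerance = 1e-12)
    # overwhelming accumulated certainty: update fades away
    r <- accumulate_field(Da, Z + 1, 1e6 * one, one, mode = md)
    expect_lt(field_sup(r - Da), 1e-5)
  }
  expect_error(accumulate_field(Da, Z, one, NULL), "certainties")
})

test_that("translation updates accumulate to the damped sum in every mode", {
  Da <- array(0, c(12, 12, 2)); Da[, , 1] <- 1
  Du <- array(0, c(12, 12, 2)); Du[, , 1] <- 0.5
  one <- matrix(1, 12, 12)
  for (md in c("additive", "compositive", "diffeomorphic")) {
    r <- accumulate_field(Da, Du, one, one, mode = md)
    expect_equal(r[, , 1], matrix(1.25, 12, 12), tolerance = 1e-12)
    expect_equal(max(abs(r[, , 2])), 0)
  }
})

test_that("diffeomorphic accumulation keeps the deformation invertible", {
  set.seed(8)
  for (trial in 1:10) {
    Da <- array(0, c(24, 24, 2))
    for (step in 1:6) {
      Du <- smooth_field(c(24, 24), runif(1, 0.5, 2), 4, trial * 10 + step)
      Da <- accumulate_field(Da, Du, mode = "diffeomorphic")
    }
    expect_gt(min(jacobian_determinant(Da)), 0)
  }
})

test_that("normalized convolution reduces to Gaussian smoothing for uniform certainty", {
  set.seed(12)
  s <- array(rnorm(24^2), c(24, 24))
  h <- array(1, c(24, 24))
  nc <- normalized_convolution(s, h, sigma2 = 2)
  plain <- morphons:::.gauss_smooth(s, sqrt(2))
  # interior agrees (boundary differs: the quotient renormalizes the mass)
  expect_equal(nc[8:17, 8:17], plain[8:17, 8:17], tolerance = 1e-9)
})

test_that("normalized convolution propagates from certain voxels and bounds amplitude", {
  # constant signal passes through unchanged wherever defined
  s <- array(3.3, c(20, 20))
  h <- array(0, c(20, 20)); h[5:15, 5:15] <- runif(121)
  out <- normalized_convolution(s, h, 2)
  expect_equal(out[4:16, 4:16], s[4:16, 4:16], tolerance = 1e-9)
  # impulse certainty: the single certain value propagates
  h1 <- array(0, c(20, 20)); h1[10, 10] <- 1
  set.seed(3)
  s1 <- array(rnorm(400), c(20, 20))
  out1 <- normalized_convolution(s1, h1, 2)
  reach <- out1[7:13, 7:13]
  expect_true(all(abs(reach - s1[10, 10]) < 1e-9))
  # sup-norm bound on random inputs
  for (i in 1:25) {
    s2 <- array(rnorm(15^2), c(15, 15))
    h2 <- array(runif(15^2), c(15, 15))
    out2 <- normalized_convolution(s2, h2, 2)
    expect_lte(max(abs(out2)), max(abs(s2)) * (1 + 1e-10))
  }
  expect_error(normalized_convolution(s, -h, 2), "non-negative")
})

test_that("regularization smooths components and propagates into uncertain areas", {
  set.seed(4)
  Da <- smooth_field(c(24, 24), 2, 3, 13)
  ca <- array(1, c(24, 24))
  r <- regularize_field(Da, ca, 2)
  expect_equal(r$field[, , 1], normalized_convolution(Da[, , 1], ca, 2))
  expect_equal(r$certainty, normalized_convolution(ca, ca, 2))
  # certainty confined to a stripe: the stripe's field extends outward
  ca2 <- array(0, c(24, 24)); ca2[11:13, ] <- 1
  Da2 <- array(0, c(24, 24, 2)); Da2[11:13, , 1] <- 1.5
  r2 <- regularize_field(Da2, ca2, 2)
  expect_gt(r2$field[16, 12, 1], 1.4)   # propagated, almost undiluted
  # amplitude bound per component
  expect_lte(max(abs(r2$field[, , 1])), 1.5 + 1e-10)
})
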