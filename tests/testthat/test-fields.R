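test_that("warping with a zero field is the identity, bit-exact", {
  set.seed(1)
  m <- array(runif(24 * 20), c(24, 20))
  expect_identical(warp_volume(m, array(0, c(24, 20, 2))), m)
  m3 <- array(runif(8^3), c(8, 8, 8))
  expect_identical(warp_volume(m3, array(0, c(8, 8, 8, 3))), m3)
})

test_that("warping is exact on linear images and matches the per-pixel oracle", {
  # constant shift of a linear ramp: interior values shift exactly
  ramp <- array(rep(1:20, 16), c(20, 16))
  D <- array(0, c(20, 16, 2)); D[, , 1] <- 2
  w <- warp_volume(ramp, D)
  expect_equal(w[1:18, ], ramp[1:18, ] + 2)
  expect_equal(w[19:20, ], ramp[c(20, 20), ])  # clamped at the far edge

  # half-voxel shift of a checkerboard equals the average of neighbours
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  Dh <- array(0, c(16, 16, 2)); Dh[, , 1] <- 0.5
  wh <- warp_volume(cb, Dh)
  expect_equal(wh[1:15, ], (cb[1:15, ] + cb[2:16, ]) / 2)

  # random smooth field vs brute-force per-pixel interpolation
  set.seed(7)
  m <- array(runif(18 * 18), c(18, 18))
  D2 <- smooth_field(c(18, 18), 2, 3, 11)
  expect_equal(warp_volume(m, D2), warp_oracle_2d(m, D2), tolerance = 1e-12)
})

test_that("warp_volume validates its inputs", {
  m <- array(0, c(8, 8))
  expect_error(warp_volume(m, array(0, c(9, 8, 2))), "grid")
  expect_error(warp_volume(m, array(0, c(8, 8, 3))), "component")
  bad <- m; bad[1] <- NA
  expect_error(warp_volume(bad, array(0, c(8, 8, 2))), "finite")
})

test_that("field warping keeps constants and matches interpolation", {
  D2 <- smooth_field(c(16, 16), 1.5, 3, 2)
  # zero second field leaves the first unchanged
  expect_equal(warp_field(D2, array(0, c(16, 16, 2))), D2)
  # constant field is invariant under resampling
  Dc <- array(0, c(16, 16, 2)); Dc[, , 1] <- 1.2; Dc[, , 2] <- -0.4
  w <- warp_field(Dc, D2)
  expect_equal(w, Dc, tolerance = 1e-12)
  # component-wise equality with the scalar resampler
  D1 <- smooth_field(c(16, 16), 2, 3, 3)
  w2 <- warp_field(D1, D2)
  expect_equal(w2[, , 1], warp_oracle_2d(D1[, , 1], D2), tolerance = 1e-12)
  expect_equal(w2[, , 2], warp_oracle_2d(D1[, , 2], D2), tolerance = 1e-12)
})

test_that("compositive accumulation has a neutral element and adds translations", {
  D <- smooth_field(c(16, 16), 2, 3, 4)
  Z <- array(0, c(16, 16, 2))
  expect_equal(compose_fields(D, Z), D)
  expect_equal(compose_fields(Z, D), D)
  c1 <- array(0, c(12, 12, 2)); c1[, , 1] <- 0.7
  c2 <- array(0, c(12, 12, 2)); c2[, , 2] <- -1.1
  expect_equal(compose_fields(c1, c2), c1 + c2, tolerance = 1e-12)
  # defining identity: D1 (+) D2 = D2 + D1 o (Id + D2)
  D1 <- smooth_field(c(16, 16), 1.5, 3, 5)
  expect_identical(compose_fields(D1, D), D + warp_field(D1, D))
})

test_that("compositive accumulation is associative within interpolation error", {
  for (s in 1:5) {
    D1 <- smooth_field(c(48, 48), 2, 8, 3 * s)
    D2 <- smooth_field(c(48, 48), 2, 8, 3 * s + 1)
    D3 <- smooth_field(c(48, 48), 2, 8, 3 * s + 2)
    lhs <- compose_fields(compose_fields(D1, D2), D3)
    rhs <- compose_fields(D1, compose_fields(D2, D3))
    expect_lt(field_sup(lhs - rhs), 0.05)
  }
})

test_that("exponential of trivial fields is exact", {
  Z <- array(0, c(10, 10, 2))
  expect_equal(exp_field(Z), Z)
  # flow of a constant field is the translation by it
  Dc <- array(0, c(12, 12, 2)); Dc[, , 1] <- 1.3; Dc[, , 2] <- -0.6
  expect_equal(exp_field(Dc), Dc, tolerance = 1e-12)
  # constant 3D field
  D3 <- array(0.8, c(6, 6, 6, 3))
  expect_equal(exp_field(D3), D3, tolerance = 1e-12)
})

test_that("exponential of a separable linear field matches the closed form", {
  # d1(x) = a * (x - c): flow is (x - c) * (e^a - 1), exact for the ODE
  n <- 33; a <- 0.04; cen <- 17
  D <- array(0, c(n, n, 2))
  D[, , 1] <- matrix(a * (seq_len(n) - cen), n, n)
  E <- exp_field(D)
  expected <- matrix((seq_len(n) - cen) * (exp(a) - 1), n, n)
  expect_equal(E[5:29, , 1], expected[5:29, ], tolerance = 0.02)
  expect_equal(max(abs(E[, , 2])), 0)
})

test_that("exponential agrees with fine-step Euler integration of the flow", {
  for (s in 1:3) {
    V <- smooth_field(c(48, 48), 3, 12, s + 20)
    E <- exp_field(V)
    flow <- euler_flow_2d(V, steps = 1024L)
    expect_lt(euler_sup_diff(E, flow), 0.08)
  }
})

test_that("exponential is invertible and obeys the semigroup property", {
  for (s in 1:4) {
    V <- smooth_field(c(48, 48), 4, 14, s + 30)
    res <- compose_fields(exp_field(-V), exp_field(V))
    expect_lt(field_sup(res), 0.2)
    sg <- compose_fields(exp_field(0.25 * V), exp_field(0.5 * V)) -
      exp_field(0.75 * V)
    expect_lt(field_sup(sg), 0.1)
    expect_gt(min(jacobian_determinant(exp_field(V))), 0)
  }
})

test_that("jacobian determinant is exact on affine deformations", {
  expect_equal(jacobian_determinant(array(0, c(8, 8, 2))), matrix(1, 8, 8))
  # uniform scaling d_i = (s - 1) x_i: det = s^ndim (exact for centered
  # differences on a linear field, interior)
  s <- 1.15; n <- 12
  D <- array(0, c(n, n, 2))
  D[, , 1] <- matrix((s - 1) * seq_len(n), n, n)
  D[, , 2] <- t(matrix((s - 1) * seq_len(n), n, n))
  jd <- jacobian_determinant(D)
  expect_equal(jd[2:(n - 1), 2:(n - 1)], matrix(s^2, n - 2, n - 2),
               tolerance = 1e-12)
  # 3D scaling
  D3 <- array(0, c(7, 7, 7, 3))
  for (a in 1:3) {
    idx <- array(0, c(7, 7, 7))
    pos <- slice.index(idx, a)
    D3[, , , a] <- (s - 1) * pos
  }
  jd3 <- jacobian_determinant(D3)
  expect_equal(jd3[3, 4, 5], s^3, tolerance = 1e-12)
})

test_that("jacobian determinant detects folding and matches the loop oracle", {
  # opposing-deformation sum folds the grid: d1 = -2 x1 gives det = -1
  n <- 9
  D <- array(0, c(n, n, 2))
  D[, , 1] <- matrix(-2 * seq_len(n), n, n)
  jd <- jacobian_determinant(D)
  expect_true(all(jd[2:(n - 1), ] < 0))
  # polynomial field vs analytic derivatives (interior, centered differences
  # are exact up to the quadratic term they cannot see; use the loop oracle)
  D2 <- smooth_field(c(14, 14), 3, 2, 9)
  expect_equal(jacobian_determinant(D2), jacobian_oracle_2d(D2),
               tolerance = 1e-12)
})
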