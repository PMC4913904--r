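test_that("level-set initialization sets +1 inside the box, -1 outside", {
  phi <- initialize_levelset(c(4, 4, 4), list(lo = c(1, 1, 1), hi = c(3, 3, 3)))
  expect_equal(sum(phi == 1), 8)
  expect_equal(sum(phi == -1), 56)

  phi2 <- initialize_levelset(c(6, 6, 6), list(lo = c(1, 1, 1), hi = c(5, 5, 5)))
  expect_true(all(phi2[2:5, 2:5, 2:5] == 1))

  expect_error(initialize_levelset(c(4, 4, 4),
                                   list(lo = c(0, 0, 0), hi = c(0, 1, 1))),
               "zero volume")
  expect_error(initialize_levelset(c(4, 4, 4),
                                   list(lo = c(1, 1, 1), hi = c(5, 3, 3))),
               "out of bounds")
})

test_that("regularized Heaviside has the arctangent form", {
  expect_equal(heaviside(0, 0.37), 0.5)
  expect_equal(heaviside(1, 1), 0.75)  # arctan(1) = pi/4
  z <- seq(-5, 5, by = 0.25)
  expect_equal(heaviside(z, 1.5) + heaviside(-z, 1.5), rep(1, length(z)))
  expect_true(all(diff(heaviside(z, 0.8)) > 0))
  expect_true(all(heaviside(z, 2) > 0 & heaviside(z, 2) < 1))
})

test_that("region means match hand evaluation on a 2-voxel grid", {
  I <- array(c(10, 2), dim = c(2, 1, 1))
  phi <- array(c(1, -1), dim = c(2, 1, 1))
  # independent scalar arithmetic: H(+-1) with epsilon = 1
  Hp <- 0.5 * (1 + 2 / pi * atan(1))
  Hm <- 0.5 * (1 + 2 / pi * atan(-1))
  m <- region_means(I, phi, epsilon = 1)
  expect_equal(m$c1, (10 * Hp + 2 * Hm) / (Hp + Hm))
  expect_equal(m$c2, (10 * (1 - Hp) + 2 * (1 - Hm)) / ((1 - Hp) + (1 - Hm)))
})

test_that("region means separate a sharp two-phase image and pool a constant", {
  I <- array(0, dim = c(4, 4, 4)); I[1:2, , ] <- 1
  phi <- array(-1, dim = c(4, 4, 4)); phi[1:2, , ] <- 1
  m <- region_means(I, phi, epsilon = 0.01)
  expect_equal(m$c1, 1, tolerance = 1e-2)
  expect_equal(m$c2, 0, tolerance = 1e-2)

  mc <- region_means(array(3.7, dim = c(3, 3, 3)), phi[1:3, 1:3, 1:3], 1)
  expect_equal(mc$c1, 3.7)
  expect_equal(mc$c2, 3.7)
})

test_that("signed pressure force is normalized to [-1, 1] with midpoint zero", {
  I <- array(c(0, 0.5, 1), dim = c(3, 1, 1))
  spf <- spf_field(I, list(c1 = 1, c2 = 0))
  expect_equal(as.vector(spf), c(-1, 0, 1))

  expect_true(all(spf_field(array(runif(27), dim = rep(3, 3)),
                            list(c1 = 0.9, c2 = 0.2)) |> abs() <= 1))

  expect_true(all(spf_field(array(2, dim = rep(3, 3)),
                            list(c1 = 2, c2 = 2)) == 0))
})

test_that("gradient magnitude is exact on linear ramps and constants", {
  n <- 8
  xs <- array(rep(0:(n - 1), each = n * n), dim = rep(n, 3))  # varies along x
  expect_equal(grad_mag3d(xs), array(1, dim = rep(n, 3)))

  ramp3 <- outer(outer(0:(n - 1), 0:(n - 1), `+`), 0:(n - 1), `+`)
  expect_equal(grad_mag3d(array(ramp3, dim = rep(n, 3))),
               array(sqrt(3), dim = rep(n, 3)))

  expect_true(all(grad_mag3d(array(5, dim = rep(4, 3))) == 0))
})

test_that("one Euler step matches a hand-evaluated update on a 3x3x3 grid", {
  I <- array(0.1, dim = c(3, 3, 3)); I[2, 2, 2] <- 0.9
  phi <- array(-1, dim = c(3, 3, 3)); phi[1:2, , ] <- 1
  p <- gfrls_params(alpha = 2, epsilon = 1, dt = 0.5)
  # independent re-evaluation by explicit loops
  H <- 0.5 * (1 + 2 / pi * atan(phi / 1))
  c1 <- sum(I * H) / sum(H); c2 <- sum(I * (1 - H)) / sum(1 - H)
  dev <- I - (c1 + c2) / 2
  spf <- dev / max(abs(dev))
  g <- array(0, dim = dim(phi))
  idx <- function(v, n) pmin(pmax(v, 1), n)
  for (z in 1:3) for (y in 1:3) for (x in 1:3) {
    dz <- if (z == 1) phi[2, y, x] - phi[1, y, x]
          else if (z == 3) phi[3, y, x] - phi[2, y, x]
          else (phi[3, y, x] - phi[1, y, x]) / 2
    dy <- if (y == 1) phi[z, 2, x] - phi[z, 1, x]
          else if (y == 3) phi[z, 3, x] - phi[z, 2, x]
          else (phi[z, 3, x] - phi[z, 1, x]) / 2
    dx <- if (x == 1) phi[z, y, 2] - phi[z, y, 1]
          else if (x == 3) phi[z, y, 3] - phi[z, y, 2]
          else (phi[z, y, 3] - phi[z, y, 1]) / 2
    g[z, y, x] <- sqrt(dz^2 + dy^2 + dx^2)
  }
  expected <- phi + 0.5 * 2 * spf * g
  expect_equal(evolve_step(phi, I, p), expected)
})

test_that("degenerate evolution steps leave phi unchanged", {
  phi <- initialize_levelset(c(4, 4, 4), list(lo = c(1, 1, 1), hi = c(3, 3, 3)))
  I <- array(0.5, dim = c(4, 4, 4))
  expect_equal(evolve_step(phi, I, gfrls_params()), phi)  # spf == 0

  flat <- array(1, dim = c(4, 4, 4))
  I2 <- array(runif(64), dim = c(4, 4, 4))
  expect_equal(evolve_step(flat, I2, gfrls_params()), flat)  # |grad phi| == 0
})

test_that("selective binary maps to {-1, +1} with zero counted inside", {
  phi <- array(c(-0.2, 0, 0.7), dim = c(3, 1, 1))
  expect_equal(as.vector(selective_binary(phi)), c(-1, 1, 1))
  b <- selective_binary(array(runif(27) - 0.5, dim = rep(3, 3)))
  expect_equal(selective_binary(b), b)           # idempotent on +-1 fields
  expect_true(all(b %in% c(-1, 1)))
  expect_true(all(selective_binary(array(-3, dim = rep(2, 3))) == -1))
})

test_that("Gaussian regularization preserves constants, bounds and mass", {
  const <- array(2.5, dim = rep(8, 3))
  expect_equal(gaussian_regularize(const, 1), const)

  phi <- initialize_levelset(rep(12, 3), list(lo = rep(3, 3), hi = rep(9, 3)))
  sm <- gaussian_regularize(phi, 1)
  expect_true(all(sm >= -1 & sm <= 1))
  expect_true(any(sm > -1 & sm < 1))   # strictly interior near the interface

  # unit impulse recovers the (separable) kernel: total mass preserved
  imp <- array(0, dim = rep(9, 3)); imp[5, 5, 5] <- 1
  expect_equal(sum(gaussian_regularize(imp, 1)), 1)
})

test_that("convergence is the sign-change fraction test", {
  a <- array(c(-1, 1), dim = c(10, 10, 10))
  expect_true(has_converged(a, a, 0))
  expect_false(has_converged(a, -a, 0.01))
  b <- a
  b[1] <- -b[1]
  expect_true(has_converged(a, b, 0.01))   # 1/1000 flipped
  expect_false(has_converged(a, b, 0))
})

test_that("segmentation recovers a noiseless two-level ellipsoid", {
  fx <- two_level_ellipsoid(c(48L, 48L, 48L))
  res <- gfrls_segment(volume3d(fx$I))
  expect_true(res$converged)
  expect_gte(dice(res$mask$data != 0, fx$truth), 0.99)
  # equals midpoint thresholding on a two-level image
  expect_gte(dice(res$mask$data != 0, fx$I > 0.5), 0.99)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  fx <- two_level_ellipsoid(c(32L, 32L, 32L))
  m1 <- gfrls_segment(volume3d(fx$I))$mask$data
  m2 <- gfrls_segment(volume3d(fx$I * 37 - 12))$mask$data
  expect_identical(m1, m2)
})

test_that("phi stays within [-1, 1] over full iterations", {
  fx <- two_level_ellipsoid(c(24L, 24L, 24L))
  res <- suppressWarnings(
    gfrls_segment(volume3d(fx$I), params = gfrls_params(max_iter = 5,
                                                        conv_tol = 0)))
  expect_true(all(res$phi >= -1 & res$phi <= 1))
})

test_that("contour expands from an interior seed without losing it", {
  fx <- two_level_ellipsoid(c(40L, 40L, 40L))
  seed <- list(lo = rep(16L, 3), hi = rep(24L, 3))
  res <- gfrls_segment(volume3d(fx$I), init_box = seed)
  traj <- res$volume_trajectory
  expect_true(all(diff(traj[seq_len(length(traj) - 1)]) >= 0))
  expect_gte(dice(res$mask$data != 0, fx$truth), 0.99)
  # the seed interior (minus a smoothing margin) stays inside the mask
  expect_true(all(res$mask$data[19:22, 19:22, 19:22] == 1))
})

test_that("contour shrinks from an enclosing box onto a bright object", {
  fx <- two_level_ellipsoid(c(40L, 40L, 40L))
  res <- gfrls_segment(volume3d(fx$I))
  traj <- res$volume_trajectory
  expect_true(all(diff(traj[seq_len(length(traj) - 1)]) <= 0))
  expect_gte(dice(res$mask$data != 0, fx$truth), 0.99)
})

test_that("a constant image converges immediately to the init box", {
  I <- array(0.4, dim = rep(16, 3))
  box <- list(lo = rep(4L, 3), hi = rep(12L, 3))
  res <- gfrls_segment(volume3d(I), init_box = box)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_equal(res$mask$data != 0, initialize_levelset(rep(16, 3), box) > 0)
})

test_that("segmentation is deterministic", {
  fx <- two_level_ellipsoid(c(24L, 24L, 24L))
  r1 <- gfrls_segment(volume3d(fx$I))
  r2 <- gfrls_segment(volume3d(fx$I))
  expect_identical(r1$mask$data, r2$mask$data)
  expect_identical(r1$phi, r2$phi)
})
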