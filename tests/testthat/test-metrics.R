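test_that("halton is the radical inverse in the given base", {
  expect_equal(halton(1:4, 2), c(1/2, 1/4, 3/4, 1/8))
  expect_equal(halton(1:2, 3), c(1/3, 2/3))
  expect_equal(halton(5, 2), 5/8)             # 101 in base 2, mirrored
  expect_equal(halton(10, 3), 1/3 + 1/27)     # 101 in base 3, mirrored
  expect_error(halton(0, 2), ">= 1")
})

test_that("halton matches digit-mirroring brute force", {
  mirror <- function(i, b) {
    digits <- integer(0)
    while (i > 0) { digits <- c(digits, i %% b); i <- i %/% b }
    sum(digits / b^seq_along(digits))
  }
  for (b in c(2, 3, 5)) {
    expect_equal(halton(1:50, b), vapply(1:50, mirror, numeric(1), b = b))
  }
})

test_that("slice area is exact on full boxes and zero on empty regions", {
  full <- matrix(TRUE, 17, 23)
  expect_equal(slice_area(full, halton_config(1000)), 17 * 23)
  expect_equal(slice_area(full, halton_config(37), pixel_area = 0.25),
               17 * 23 * 0.25)
  expect_equal(slice_area(matrix(FALSE, 8, 8)), 0)
})

test_that("slice area of a disk approaches its pixel count", {
  n <- 64
  d2 <- outer(((1:n) - 32.5)^2, ((1:n) - 32.5)^2, `+`)
  disk <- d2 <= 30^2
  est <- slice_area(disk, halton_config(1e5))
  expect_lt(abs(est - sum(disk)) / sum(disk), 0.01)
  expect_lt(abs(est - pi * 30^2) / (pi * 30^2), 0.01)
})

test_that("halton volumes converge to the voxel-count volume", {
  sph <- sphere_mask(32, 10)
  ref <- voxel_volume(sph, spacing = c(1, 1, 1))
  expect_equal(ref, sum(sph))
  errs <- vapply(c(1e3, 1e4, 1e5), function(N)
    abs(estimate_volume(sph, cfg = halton_config(N),
                        spacing = c(1, 1, 1)) - ref) / ref, numeric(1))
  expect_true(all(diff(errs) <= 0))
  expect_lt(errs[3], 0.02)
  # and the discrete sphere is within 2% of the analytic ball volume
  expect_lt(abs(estimate_volume(sph, cfg = halton_config(1e5),
                                spacing = c(1, 1, 1)) - 4 / 3 * pi * 1000) /
              (4 / 3 * pi * 1000), 0.02)
})

test_that("volumes honour labels and spacing", {
  cube <- array(0L, dim = c(16, 16, 16))
  cube[4:13, 4:13, 4:13] <- 2L
  lab <- label_volume(cube, spacing = c(1, 1, 1))
  expect_equal(voxel_volume(lab, "dentine"), 1000)
  expect_equal(voxel_volume(lab, "dentine", spacing = c(2, 1, 1)), 2000)
  expect_equal(voxel_volume(lab, "pulp"), 0)
  expect_equal(estimate_volume(lab, "pulp", halton_config(100)), 0)
  expect_lt(abs(estimate_volume(lab, "dentine", halton_config(1e4)) - 1000) /
              1000, 0.01)
  expect_error(voxel_volume(lab, "crown"), "unknown label")
})

test_that("relative error is the signed fraction", {
  expect_equal(relative_error(110, 100), 0.10)
  expect_equal(relative_error(100, 100), 0)
  expect_equal(relative_error(8246.29, 8167), (8246.29 - 8167) / 8167)
  expect_lt(relative_error(90, 100), 0)
  expect_error(relative_error(1, 0), "positive")
})

test_that("volume MAD is the mean absolute deviation", {
  expect_equal(volume_mad(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(volume_mad(110, 100), 10)
  expect_equal(volume_mad(c(110, 90), c(100, 100)), 10)
  # linear under unit change
  x <- c(8246.29, 47740.8); y <- c(8167, 49700)
  expect_equal(volume_mad(10 * x, 10 * y), 10 * volume_mad(x, y))
})

test_that("corrco is the absolute Pearson correlation", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(corrco(x, x), 1)
  expect_equal(corrco(x, -x), 1)
  expect_equal(corrco(c(1, 2, 3), c(1, 3, 2)), 0.5)
  # invariant to affine maps of either argument
  y <- c(2, 1, 4, 3, 9)
  expect_equal(corrco(x, y), corrco(3 * x - 7, y))
  expect_equal(corrco(x, y), corrco(y, x))
  expect_equal(corrco(x, y), abs(cor(x, y)))
  expect_error(corrco(rep(1, length(x)), x), "constant")
})

test_that("overlap indexes follow the set formulas", {
  A <- array(FALSE, dim = c(4, 4, 4)); A[1:2, , ] <- TRUE
  expect_equal(overlap_indexes(A, A), c(S = 1, SENS = 1, SPEC = 1))

  D <- array(FALSE, dim = c(4, 4, 4)); D[3:4, , ] <- TRUE
  expect_equal(overlap_indexes(A, D), c(S = 0, SENS = 0, SPEC = 0))

  # D inside A with |A| = 2|D|
  D2 <- array(FALSE, dim = c(4, 4, 4)); D2[1, , ] <- TRUE
  expect_equal(overlap_indexes(A, D2), c(S = 2/3, SENS = 1, SPEC = 1/2))

  expect_error(overlap_indexes(A, array(FALSE, dim = c(4, 4, 4))), "empty")
})

test_that("otsu threshold matches an exhaustive between-class variance scan", {
  brute <- function(x) {
    cand <- seq(0.01, 0.99, by = 0.002)
    bcv <- vapply(cand, function(t) {
      a <- x[x < t]; b <- x[x >= t]
      if (!length(a) || !length(b)) return(-Inf)
      length(a) / length(x) * length(b) / length(x) * (mean(a) - mean(b))^2
    }, numeric(1))
    cand[which.max(bcv)]
  }
  set.seed(4)
  x <- c(rnorm(400, 0.5, 0.03), rnorm(200, 0.95, 0.02))
  x <- pmin(pmax(x, 0), 1)
  thr <- otsu_threshold(x)
  # same induced classification as the brute-force optimum
  expect_equal(x >= thr, x >= brute(x))
  expect_gt(thr, 0.55); expect_lt(thr, 0.93)   # splits between the modes
})

test_that("metrics report aggregates volumes, overlap and agreement", {
  set.seed(5)
  truth <- array(0L, dim = c(12, 16, 16))
  truth[3:10, 3:8, 3:8] <- 2L
  truth[3:10, 10:14, 10:14] <- 3L
  truth[5:8, 5:6, 5:6] <- 1L
  pred <- truth
  pred[3, 3, 3:5] <- 0L   # small disagreement
  rep <- metrics_report(label_volume(pred), label_volume(truth),
                        halton_config(2e4))
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep$per_structure), 3)
  expect_true(all(rep$per_structure$S > 0.9))
  expect_gt(rep$corrco, 0.99)
  expect_gte(rep$mad, 0)
})
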