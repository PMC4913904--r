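# Shared fixture builders. Everything is generated in code; no binary files.

# squared normalized ellipsoid coordinate on an (nz, ny, nx) grid, 0-based
ellipsoid_field <- function(shape, center, axes) {
  z <- ((seq_len(shape[1]) - 1) - center[1]) / axes[1]
  y <- ((seq_len(shape[2]) - 1) - center[2]) / axes[2]
  x <- ((seq_len(shape[3]) - 1) - center[3]) / axes[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`)
}

# two-level image: bright ellipsoid on dark background; returns image + truth
two_level_ellipsoid <- function(shape = c(48L, 48L, 48L),
                                lo = 0.1, hi = 0.9) {
  c0 <- (shape - 1) / 2
  axes <- shape * c(0.35, 0.28, 0.28)
  inside <- ellipsoid_field(shape, c0, axes) <= 1
  I <- array(lo, dim = shape)
  I[inside] <- hi
  list(I = I, truth = inside)
}

# centered solid sphere mask (logical 3D array)
sphere_mask <- function(n = 32L, radius = 10) {
  c0 <- (n - 1) / 2
  d2 <- ellipsoid_field(c(n, n, n), rep(c0, 3), rep(radius, 3))
  array(d2 <= 1, dim = c(n, n, n))
}

# three-tier concentric-square slice, dark outermost (the tier ordering of
# the tooth phantom), with Gaussian noise; returns stimulus + tier truth
three_tier_slice <- function(n = 96L, means = c(0.35, 0.65, 0.95),
                             noise_sd = 0.02, seed = 7L) {
  S <- matrix(means[1], n, n)
  truth <- matrix(1L, n, n)
  m1 <- (n %/% 4):(3 * n %/% 4)
  m2 <- (n %/% 3):(2 * n %/% 3)
  S[m1, m1] <- means[2]; truth[m1, m1] <- 2L
  S[m2, m2] <- means[3]; truth[m2, m2] <- 3L
  if (noise_sd > 0) {
    set.seed(seed)
    S <- pmin(pmax(S + stats::rnorm(n * n, sd = noise_sd), 0), 1)
    dim(S) <- c(n, n)
  }
  list(S = S, truth = truth)
}

# Dice coefficient of two binary arrays (independent of overlap_indexes)
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small fast phantom spec for unit tests
test_phantom_spec <- function(shape = c(64L, 64L, 64L), ...) {
  phantom_spec(shape = shape, ...)
}
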