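#' The 3x3 synaptic weight kernel
#'
#' Weight matrix of the 3x3 neighborhood used by both the feeding and linking
#' channels: 0.1 for the 4-connected neighbors, 0.07 for the diagonals, zero
#' center (a neuron does not stimulate itself).
#'
#' @return A 3x3 numeric matrix.
#' @export
pcnn_kernel <- function() {
  matrix(c(0.07, 0.1, 0.07,
           0.1,  0,   0.1,
           0.07, 0.1, 0.07), nrow = 3, byrow = TRUE)
}

#' Parameters of the improved PCNN classifier
#'
#' Constants of the pulse-coupled neural network lattice (one neuron per
#' pixel) with the hierarchical graded output. The graded output
#' \eqn{Y = \xi / \max\xi \cdot k} with \eqn{\xi = U - \theta} replaces the
#' binary step nonlinearity of the classic model, so the threshold gain
#' `vTheta` must stay of the order of the internal activity: a very large
#' value (the classic firing-reset convention) drives \eqn{\xi} negative for
#' every neuron and collapses all hierarchy levels.
#'
#' @param beta linking strength.
#' @param vF,vL,vTheta normalizing constants of the feeding, linking and
#'   threshold channels.
#' @param aF,aL,aTheta exponential decay coefficients (>= 0).
#' @param dt time constant \eqn{\Delta t}.
#' @param W 3x3 linking kernel (zero center).
#' @param M 3x3 feeding kernel; defaults to `W`, the standard simplification.
#' @param k hierarchy count: number of intensity tiers the output resolves.
#' @param n_iter number of iterations N.
#' @param fire_level fraction of `k` above which a neuron counts as firing for
#'   the `firate` telemetry counter.
#' @return A list of class `pcnn_params`.
#' @export
pcnn_params <- function(beta = 0.2, vF = 0.1, vL = 0.2, vTheta = 0.1,
                        aF = 0.1, aL = 0.3, aTheta = 0.2, dt = 1,
                        W = pcnn_kernel(), M = W, k = 3L, n_iter = 10L,
                        fire_level = 0.5) {
  stopifnot(aF >= 0, aL >= 0, aTheta >= 0, dt > 0, k >= 1, n_iter >= 1)
  check_kernel <- function(K, nm) {
    if (!is.matrix(K) || !all(dim(K) == c(3L, 3L)) || K[2, 2] != 0)
      stop("`", nm, "` must be a 3x3 kernel with zero center")
  }
  check_kernel(W, "W"); check_kernel(M, "M")
  structure(list(beta = beta, vF = vF, vL = vL, vTheta = vTheta,
                 aF = aF, aL = aL, aTheta = aTheta, dt = dt, W = W, M = M,
                 k = as.integer(k), n_iter = as.integer(n_iter),
                 fire_level = fire_level),
            class = "pcnn_params")
}

#' Initialize the PCNN state
#'
#' All per-neuron grids (feeding F, linking L, internal activity U, threshold
#' theta, output Y, firing counter) start at zero, so that the first
#' iteration's internal activity equals the external stimulus.
#'
#' @param S 2D stimulus matrix (pixel intensities in `[0, 1]`).
#' @return A list of class `pcnn_state` with elements `F`, `L`, `U`, `theta`,
#'   `Y`, `firate`, `n`.
#' @export
pcnn_init <- function(S) {
  if (!is.matrix(S) || !length(S)) stop("`S` must be a nonempty matrix")
  if (!all(is.finite(S))) stop("stimulus contains non-finite values")
  z <- matrix(0, nrow(S), ncol(S))
  structure(list(F = z, L = z, U = z, theta = z, Y = z,
                 firate = matrix(0L, nrow(S), ncol(S)), n = 0L),
            class = "pcnn_state")
}

# 3x3 correlation with zero padding (missing neighbors contribute 0)
correlate3x3 <- function(Y, K) {
  out <- matrix(0, nrow(Y), ncol(Y))
  for (r in -1:1) for (t in -1:1) {
    w <- K[r + 2, t + 2]
    if (w == 0) next
    out <- out + w * shift2d_zero(Y, r, t)
  }
  out
}

# shift a matrix by (dr, dc): out[i, j] = Y[i + dr, j + dc], zero outside
shift2d_zero <- function(Y, dr, dc) {
  n <- nrow(Y); m <- ncol(Y)
  out <- matrix(0, n, m)
  ri <- max(1, 1 - dr):min(n, n - dr)
  ci <- max(1, 1 - dc):min(m, m - dc)
  out[ri, ci] <- Y[ri + dr, ci + dc]
  out
}

#' Feeding channel update
#'
#' \deqn{F(n) = e^{-\alpha_F \Delta t} F(n-1) + S + V_F (M \ast Y(n-1)),}
#' where the 3x3 correlation uses zero padding at the image border.
#'
#' @param state a `pcnn_state` (holding `F` and `Y` at iteration n-1).
#' @param S stimulus matrix.
#' @param params a [pcnn_params()].
#' @return The updated feeding matrix.
#' @export
pcnn_feeding <- function(state, S, params = pcnn_params()) {
  exp(-params$aF * params$dt) * state$F + S +
    params$vF * correlate3x3(state$Y, params$M)
}

#' Linking channel update
#'
#' \deqn{L(n) = e^{-\alpha_L \Delta t} L(n-1) + V_L (W \ast Y(n-1))}
#' (no stimulus term).
#'
#' @inheritParams pcnn_feeding
#' @return The updated linking matrix.
#' @export
pcnn_linking <- function(state, params = pcnn_params()) {
  exp(-params$aL * params$dt) * state$L +
    params$vL * correlate3x3(state$Y, params$W)
}

#' Internal activity
#'
#' Multiplicative modulation of the feeding channel by the linking channel:
#' \eqn{U = F (1 + \beta L)}.
#'
#' @param F,L feeding and linking matrices.
#' @param beta linking strength.
#' @return The internal activity matrix.
#' @export
pcnn_internal_activity <- function(F, L, beta) {
  F * (1 + beta * L)
}

#' Dynamic threshold update
#'
#' \deqn{\theta(n) = e^{-\alpha_\theta \Delta t} \theta(n-1) +
#'   V_\theta Y(n-1):}
#' exponential decay plus a recharge proportional to the previous output.
#'
#' @inheritParams pcnn_feeding
#' @return The updated threshold matrix.
#' @export
pcnn_threshold_update <- function(state, params = pcnn_params()) {
  exp(-params$aTheta * params$dt) * state$theta + params$vTheta * state$Y
}

#' Hierarchical graded pulse output
#'
#' Replaces the binary step output of the classic model with a graded,
#' k-level output:
#' \deqn{\xi = U - \theta, \qquad
#'   G_{ij} = \sum_{r,t \in \{-1,0,1\}} |\xi_{ij} - \xi_{i+r,j+t}|, \qquad
#'   Y_{ij} = \frac{\xi_{ij}}{\max \xi} \, k.}
#' `G` measures the local variation of \eqn{\xi} in the 3x3 window
#' (out-of-grid neighbors are skipped); it is returned as a diagnostic and
#' does not enter `Y`. If `max(xi)` is 0 the output is identically zero.
#'
#' @param U internal activity matrix.
#' @param theta threshold matrix.
#' @param k hierarchy count (>= 1).
#' @param use_edge_weight if `TRUE`, divide \eqn{\xi} by \eqn{(1 + \lambda G)}
#'   before normalization (experimental edge-aware variant, off by default).
#' @param lambda weight of the edge term when `use_edge_weight = TRUE`.
#' @return List with matrices `xi`, `G`, `Y`.
#' @export
pcnn_improved_output <- function(U, theta, k, use_edge_weight = FALSE,
                                 lambda = 0.1) {
  stopifnot(k >= 1)
  xi <- U - theta
  G <- local_variation3x3(xi)
  xw <- if (use_edge_weight) xi / (1 + lambda * G) else xi
  mx <- max(xw)
  Y <- if (mx == 0) matrix(0, nrow(xi), ncol(xi)) else xw / mx * k
  list(xi = xi, G = G, Y = Y)
}

# sum over the 8 in-grid neighbors of |xi_ij - xi_neighbor|
local_variation3x3 <- function(xi) {
  n <- nrow(xi); m <- ncol(xi)
  G <- matrix(0, n, m)
  for (r in -1:1) for (t in -1:1) {
    if (r == 0 && t == 0) next
    ri <- max(1, 1 - r):min(n, n - r)
    ci <- max(1, 1 - t):min(m, m - t)
    G[ri, ci] <- G[ri, ci] + abs(xi[ri, ci] - xi[ri + r, ci + t])
  }
  G
}

#' Run the improved PCNN on one slice
#'
#' Executes `n_iter` iterations of the lattice dynamics. Per iteration, in
#' order: linking, feeding, internal activity, threshold (from the previous
#' output, so that both the threshold recursion and the output formula see
#' consistent iteration indices), then the hierarchical graded output. The
#' firing counter accumulates, per pixel, the iterations in which
#' `Y >= fire_level * k`. The computation is deterministic.
#'
#' @param S 2D stimulus matrix with values in `[0, 1]`.
#' @param params a [pcnn_params()].
#' @return List with `Y` (final graded output), `firate` (integer matrix),
#'   and `state` (full final `pcnn_state`).
#' @export
pcnn_run <- function(S, params = pcnn_params()) {
  if (min(S) < 0 || max(S) > 1)
    stop("stimulus must lie in [0, 1]; normalize the volume first")
  state <- pcnn_init(S)
  for (n in seq_len(params$n_iter)) {
    L <- pcnn_linking(state, params)
    F <- pcnn_feeding(state, S, params)
    U <- pcnn_internal_activity(F, L, params$beta)
    theta <- pcnn_threshold_update(state, params)
    out <- pcnn_improved_output(U, theta, params$k)
    state$L <- L; state$F <- F; state$U <- U
    state$theta <- theta; state$Y <- out$Y
    state$firate <- state$firate +
      (out$Y >= params$fire_level * params$k)
    state$n <- n
  }
  list(Y = state$Y, firate = state$firate, state = state)
}

#' Integer classes from the graded PCNN output
#'
#' Bins the graded output into `k + 1` classes by rounding after clamping to
#' `[0, k]`; pixels with equal output get equal class.
#'
#' @param Y graded output matrix (or array).
#' @param k hierarchy count.
#' @return Integer array of classes in `0..k`, same shape as `Y`.
#' @export
labels_from_output <- function(Y, k) {
  stopifnot(k >= 1)
  out <- as.integer(round(pmin(pmax(Y, 0), k)))
  if (!is.null(dim(Y))) dim(out) <- dim(Y)
  out
}
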