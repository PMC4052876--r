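## The orientation-gated Gaussian kernel.  Conformational differences are
## small compared with orientational ones, so the kernel only compares
## snapshots whose viewing directions are (nearly) the same:
##     W_ij = exp(-D_ij^2 / (2 sigma^2))   if  dtheta_ij <= theta_eps,
##          = 0                            otherwise,
## and within each row only the k_nn smallest gate-open distances are kept,
## after which W is symmetrized by union.  At a sufficiently small theta_eps
## the residual in-gate variation is dominated by conformation.

#' Gating parameters
#'
#' @param theta_epsilon angular gate in radians (conventionally two Shannon
#'   angles, see [shannon_angle()]); `Inf` disables the gate.
#' @param k_nn nearest neighbours kept per row among gate-open pairs.
#' @param sigma Gaussian kernel width in distance units, or `"auto"` to use
#'   [select_sigma()].
#' @param delta_theta `"viewing_axis"` (great-circle angle between viewing
#'   directions, default) or `"so3"` (full misorientation angle).
#' @return object of class `gating_params`.
#' @export
gating_params <- function(theta_epsilon = 0.08, k_nn = 3, sigma = "auto",
                          delta_theta = c("viewing_axis", "so3")) {
  if (theta_epsilon <= 0) stop_confmap("theta_epsilon must be > 0")
  if (k_nn < 1) stop_confmap("k_nn must be >= 1")
  structure(list(theta_epsilon = theta_epsilon, k_nn = as.integer(k_nn),
                 sigma = sigma, delta_theta = match.arg(delta_theta)),
            class = "gating_params")
}

pairwise_misorientation <- function(quaternions) {
  g <- abs(tcrossprod(quaternions))      # |<q_i, q_j>|, q ~ -q identified
  g[g > 1] <- 1
  2 * acos(g)
}

#' Build the orientation-gated kernel
#'
#' @param D symmetric distance matrix (from [pairwise_distances()]).
#' @param orientations `n x 4` matrix of unit quaternions, or `NULL` when
#'   `theta_epsilon = Inf` (ungated).
#' @param params a [gating_params()].
#' @return sparse symmetric kernel (class `dgCMatrix`), with the selected
#'   `sigma` in attribute `"sigma"`.
#' @export
gated_kernel <- function(D, orientations, params) {
  stopifnot(inherits(params, "gating_params"))
  D <- unclass(D)
  n <- nrow(D)
  if (is.finite(params$theta_epsilon)) {
    if (is.null(orientations) || nrow(orientations) != n)
      stop_confmap("gating needs one orientation per snapshot")
    ang <- switch(params$delta_theta,
                  viewing_axis = pairwise_viewing_angles(orientations),
                  so3 = pairwise_misorientation(orientations))
    open <- ang <= params$theta_epsilon
  } else {
    open <- matrix(TRUE, n, n)
  }
  diag(open) <- FALSE
  deg <- rowSums(open)
  if (any(deg == 0))
    stop_confmap("snapshot %d has no gate-open neighbour: increase theta_epsilon or k_nn",
                 which(deg == 0)[1])

  sigma <- params$sigma
  if (identical(sigma, "auto")) sigma <- select_sigma(D, open)

  ## per-row k-NN among gate-open entries (ties broken by snapshot index)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    cand <- which(open[i, ])
    keep <- cand[order(D[i, cand], cand)][seq_len(min(params$k_nn, length(cand)))]
    ii <- c(ii, rep.int(i, length(keep))); jj <- c(jj, keep)
  }
  w <- exp(-D[cbind(ii, jj)]^2 / (2 * sigma^2))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W <- pmax_sparse(W, Matrix::t(W))      # symmetrize by union
  attr(W, "sigma") <- sigma
  attr(W, "theta_epsilon") <- params$theta_epsilon
  attr(W, "k_nn") <- params$k_nn
  W
}

## elementwise max of two sparse non-negative matrices
pmax_sparse <- function(A, B) {
  M <- Matrix::drop0((A + B + abs(A - B)) / 2)
  methods::as(M, "generalMatrix")
}

#' Automatic kernel bandwidth from the pairwise-distance spectrum
#'
#' Scans `S(sigma) = sum_ij exp(-D_ij^2 / (2 sigma^2))` (over gate-open pairs
#' plus the diagonal) on a log-spaced sigma grid.  `log S` rises from `n`
#' (only self-pairs count) to the number of open pairs as `sigma` sweeps the
#' distance scale; the returned `sigma` is the log-midpoint of the region
#' where the slope of `log S` vs `log sigma` is near-maximal — the standard
#' bandwidth diagnostic for diffusion-map kernels.
#'
#' @param D symmetric distance matrix.
#' @param gate_mask logical matrix of admissible pairs (default: all
#'   off-diagonal pairs).
#' @param slope_fraction slopes above this fraction of the maximum define
#'   the linear region (default 0.25; the region midpoint then tracks the
#'   centre of the kernel-sum transition).
#' @return scalar bandwidth.
#' @export
select_sigma <- function(D, gate_mask = NULL, slope_fraction = 0.25) {
  D <- unclass(D)
  n <- nrow(D)
  if (is.null(gate_mask)) {
    gate_mask <- matrix(TRUE, n, n); diag(gate_mask) <- FALSE
  }
  d <- D[gate_mask & upper.tri(D)]
  d <- d[is.finite(d)]
  if (!length(d) || all(d == 0))
    stop_confmap("degenerate distances: no positive gate-open distance to scan")
  lo <- max(min(d[d > 0]) / 10, max(d) * 1e-6)
  hi <- max(d) * 10
  sig <- exp(seq(log(lo), log(hi), length.out = 80))
  logS <- vapply(sig, function(s)
    log(n + 2 * sum(exp(-d^2 / (2 * s^2)))), numeric(1))
  slope <- diff(logS) / diff(log(sig))
  smax <- max(slope)
  if (smax <= 1e-8)
    stop_confmap("no linear region in the log S(sigma) scan (degenerate distances)")
  ## contiguous near-maximal-slope region containing the argmax
  ok <- slope >= slope_fraction * smax
  i0 <- which.max(slope)
  a <- i0; while (a > 1 && ok[a - 1]) a <- a - 1
  b <- i0; while (b < length(slope) && ok[b + 1]) b <- b + 1
  exp((log(sig[a]) + log(sig[b + 1])) / 2)
}
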