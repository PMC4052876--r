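## Spectral embeddings: diffusion maps (density-normalized Markov-chain
## eigenvectors of a Gaussian kernel) and Isomap (classical MDS of graph
## geodesics on the k-NN graph).

#' Diffusion-map embedding
#'
#' Given a symmetric non-negative kernel `W`, forms the density-normalized
#' kernel `W' = Dg^-alpha W Dg^-alpha` (`Dg = diag(rowSums(W))`; `alpha = 1`
#' recovers the Laplace-Beltrami operator independently of the sampling
#' density), the Markov matrix `M = Dg'^-1 W'`, and returns its leading
#' eigenvalues and right eigenvectors computed through the symmetric
#' conjugate `Dg'^1/2 M Dg'^-1/2`.  The top eigenvalue is 1 with a constant
#' eigenvector psi1; the embedding coordinates are psi2, psi3, ....
#'
#' @param W symmetric non-negative kernel matrix (dense or `Matrix` sparse),
#'   e.g. from [gated_kernel()]; its graph must be connected.
#' @param n_components number of non-trivial coordinates to return.
#' @param alpha density-normalization exponent (0, 1/2 or 1; default 1).
#' @param scaled if `TRUE`, scale coordinate l by its eigenvalue
#'   `lambda_(l+1)`; default raw eigenvectors.
#' @param allow_disconnected eigendecompose a disconnected kernel instead of
#'   erroring (the unit eigenvalue then has one multiplicity per component).
#' @return object of class `confmap_embedding`: list with `eigenvalues`
#'   (descending, length `n_components + 1`, including the trivial 1),
#'   `coordinates` (`n x n_components`, columns psi2..), `psi1`, `method`,
#'   and the normalization parameters.
#' @export
diffusion_map <- function(W, n_components = 5, alpha = 1, scaled = FALSE,
                          allow_disconnected = FALSE) {
  sigma_attr <- attr(W, "sigma")
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  n <- nrow(W)
  if (n != ncol(W)) stop_confmap("W must be square")
  if (max(abs(W - Matrix::t(W))) > 1e-9) stop_confmap("W must be symmetric")
  if (length(W@x) && min(W@x) < 0) stop_confmap("W must be non-negative")
  n_components <- min(n_components, n - 1)

  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  ncomp <- igraph::components(g)$no
  if (ncomp > 1 && !allow_disconnected)
    stop_confmap("kernel graph has %d connected components: increase theta_epsilon or k_nn",
                 ncomp)

  d <- Matrix::rowSums(W)
  if (any(d == 0)) stop_confmap("kernel has an isolated vertex (zero row sum)")
  if (alpha != 0) {
    Dg <- Matrix::Diagonal(x = d^(-alpha))
    W <- Dg %*% W %*% Dg              # density normalization
  }
  d1 <- Matrix::rowSums(W)
  Ds <- Matrix::Diagonal(x = 1 / sqrt(d1))
  S <- Matrix::forceSymmetric(Ds %*% W %*% Ds)  # symmetric conjugate of the Markov matrix

  nev <- n_components + 1
  if (n <= 1200 || ncomp > 1) {
    es <- eigen(as.matrix(S), symmetric = TRUE)
    vals <- es$values[seq_len(nev)]
    vecs <- es$vectors[, seq_len(nev), drop = FALSE]
  } else {
    Sg <- methods::as(S, "generalMatrix")
    ar <- igraph::arpack(function(x, extra = NULL) as.vector(Sg %*% x),
                         sym = TRUE,
                         options = list(n = n, nev = nev,
                                        ncv = min(n, max(4 * nev, 40)),
                                        which = "LA", maxiter = 10000))
    ord <- order(ar$values, decreasing = TRUE)
    vals <- ar$values[ord]
    vecs <- ar$vectors[, ord, drop = FALSE]
  }
  psi <- vecs * (1 / sqrt(d1))         # right eigenvectors of M
  psi <- apply(psi, 2, function(v) v / sqrt(sum(v^2)))
  psi <- fix_signs(psi)
  coords <- psi[, -1, drop = FALSE]
  if (scaled) coords <- sweep(coords, 2, vals[-1], `*`)
  structure(list(eigenvalues = vals, coordinates = coords, psi1 = psi[, 1],
                 method = "diffusion_map", alpha = alpha,
                 sigma = sigma_attr, scaled = scaled),
            class = "confmap_embedding")
}

## deterministic sign convention: the entry of largest magnitude is positive
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Isomap embedding
#'
#' Geodesic distances by shortest paths on the k-nearest-neighbour graph of
#' `D`, followed by classical multidimensional scaling.
#'
#' @param D symmetric distance matrix.
#' @param k_nn neighbours per row (graph symmetrized by union).
#' @param n_components embedding dimension.
#' @return a `confmap_embedding` with `method = "isomap"`; `coordinates` are
#'   the top principal coordinates, `eigenvalues` the MDS eigenvalues.
#' @export
isomap <- function(D, k_nn = 6, n_components = 3) {
  D <- unclass(D)
  n <- nrow(D)
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    keep <- cand[order(D[i, cand], cand)][seq_len(min(k_nn, n - 1))]
    ii <- c(ii, rep.int(i, length(keep))); jj <- c(jj, keep)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ii, to = jj, weight = D[cbind(ii, jj)]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "min")
  if (igraph::components(g)$no > 1)
    stop_confmap("k-NN graph is disconnected: increase k_nn")
  geo <- igraph::distances(g, algorithm = "dijkstra")
  ord <- as.integer(igraph::V(g)$name)
  geo <- geo[order(ord), order(ord)]
  mds <- stats::cmdscale(geo, k = n_components, eig = TRUE)
  coords <- fix_signs(unname(mds$points))
  structure(list(eigenvalues = mds$eig[seq_len(n_components)],
                 coordinates = coords, psi1 = NULL,
                 method = "isomap", k_nn = k_nn),
            class = "confmap_embedding")
}

#' @export
print.confmap_embedding <- function(x, ...) {
  cat(sprintf("<confmap_embedding> %s, %d snapshots x %d components\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  cat("eigenvalues:", format(signif(x$eigenvalues, 4)), "\n")
  invisible(x)
}

#' Export an embedding as CSV
#'
#' Writes eigenvalues (comment header) and per-snapshot coordinates.
#' @param embedding a `confmap_embedding`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# method: %s", embedding$method),
               paste0("# eigenvalues: ",
                      paste(format(embedding$eigenvalues, digits = 12),
                            collapse = " "))), con)
  df <- as.data.frame(embedding$coordinates)
  names(df) <- paste0("psi", seq_len(ncol(df)) + 1)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
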