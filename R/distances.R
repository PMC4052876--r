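## Pairwise snapshot distances.
##
## The double-filtered distance removes the defocus dependence of cryo-EM
## snapshots: before comparing snapshots i and j, each is convolved with the
## OTHER snapshot's point-spread function,
##     D_ij = || PSF_j (x) I_i  -  PSF_i (x) I_j ||.
## If I_i = PSF_i (x) P and I_j = PSF_j (x) P come from the same projected
## potential P at different defocus, both terms equal PSF_i (x) PSF_j (x) P
## and the distance vanishes identically.  Convolutions are circular and the
## computation is done in Fourier space (multiplication by the CTF), with a
## 1/sqrt(p) Parseval factor so the Fourier-space value equals the real-space
## l2 norm.

#' Euclidean distance between two snapshots
#'
#' @param image_i,image_j numeric matrices of equal shape.
#' @return the l2 norm of the pixelwise difference.
#' @export
euclidean_distance <- function(image_i, image_j) {
  if (!all(dim(image_i) == dim(image_j))) stop_confmap("image shapes differ")
  sqrt(sum((image_i - image_j)^2))
}

#' Defocus-invariant double-filtered distance
#'
#' `D_ij = || CTF_j * FT(I_i) - CTF_i * FT(I_j) || / sqrt(p)`: each snapshot
#' is filtered by the other's CTF before differencing, so two snapshots of
#' the same projection recorded at different defocus are at distance zero.
#' Symmetric in (i, j).
#'
#' @param image_i,image_j numeric matrices of equal shape.
#' @param ctf_i,ctf_j real CTF filter matrices (frequency layout of
#'   [stats::fft()]), same shape as the images.
#' @return non-negative scalar, in the same units as the real-space l2 norm.
#' @export
double_filtered_distance <- function(image_i, ctf_i, image_j, ctf_j) {
  dims <- dim(image_i)
  if (!all(dim(image_j) == dims) || !all(dim(ctf_i) == dims) ||
      !all(dim(ctf_j) == dims))
    stop_confmap("images and CTF filters must share one shape")
  d <- ctf_j * fft2(image_i) - ctf_i * fft2(image_j)
  sqrt(sum(Mod(d)^2) / length(image_i))
}

#' All pairwise snapshot distances
#'
#' Computes the full symmetric distance matrix of a snapshot stack, either
#' plain Euclidean or double-filtered (which requires per-snapshot CTF
#' metadata).  Snapshots are variance-normalized first by default, matching
#' the usual preprocessing of low-dose images.
#'
#' Both kinds are evaluated with dense linear algebra: for the
#' double-filtered kind,
#' `D_ij^2 = sum_k CTF_j^2 |F_i|^2 + CTF_i^2 |F_j|^2 - 2 CTF_i CTF_j Re(F_i conj(F_j))`
#' decomposes into three n x n matrix products.
#'
#' @param stack a [snapshot_stack()].
#' @param kind `"euclidean"` or `"double_filtered"`.
#' @param normalize variance-normalize each snapshot first (default `TRUE`).
#' @param resolution optional analysis resolution in Angstrom: Fourier
#'   components beyond `1/resolution` are excluded from the comparison
#'   (low-pass matched to the information content of the snapshots; the
#'   noise is white, so comparing empty high-frequency shells only adds
#'   variance to every distance).  `NULL` compares the full band.
#' @param mask_radius optional real-space circular mask radius in Angstrom
#'   (soft cosine edge), applied after normalization.  Restricting the
#'   comparison to the particle support removes the noise carried by empty
#'   background pixels; standard practice for image stacks, meaningless for
#'   diffraction patterns (which are delocalized).
#' @return a symmetric `n x n` matrix with class attribute
#'   `confmap_distances` and attribute `kind`.
#' @export
pairwise_distances <- function(stack, kind = c("euclidean", "double_filtered"),
                               normalize = TRUE, resolution = NULL,
                               mask_radius = NULL) {
  kind <- match.arg(kind)
  X <- stack_matrix(stack)                 # n x p
  n <- nrow(X)
  if (n < 2) stop_confmap("need at least 2 snapshots")
  if (normalize) {
    mu <- rowMeans(X)
    s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
    if (any(s == 0)) stop_confmap("constant snapshot cannot be normalized")
    X <- (X - mu) / s
  }
  side <- stack$side
  if (!is.null(mask_radius)) {
    g <- grid_coords(side, stack$pixel_size)
    r <- sqrt(outer(g^2, g^2, `+`))
    edge <- 2 * stack$pixel_size
    m <- as.vector(ifelse(r <= mask_radius, 1,
                          ifelse(r >= mask_radius + edge, 0,
                                 0.5 * (1 + cos(pi * (r - mask_radius) / edge)))))
    X <- X * rep(m, each = n)
  }
  keep <- NULL                             # Fourier components compared
  if (!is.null(resolution)) {
    if (resolution < 2 * stack$pixel_size)
      stop_confmap("resolution %.3g A is finer than Nyquist (%g A)",
                   resolution, 2 * stack$pixel_size)
    keep <- which(as.vector(freq_radius(side, stack$pixel_size)) <= 1 / resolution)
  }
  if (kind == "euclidean" && is.null(keep)) {
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  } else {
    p <- side * side
    if (is.null(keep)) keep <- seq_len(p)
    Fr <- matrix(0, n, length(keep)); Fi <- matrix(0, n, length(keep))
    for (i in seq_len(n)) {
      f <- as.vector(fft2(matrix(X[i, ], side, side)))[keep]
      Fr[i, ] <- Re(f); Fi[i, ] <- Im(f)
    }
    if (kind == "euclidean") {
      A <- Fr^2 + Fi^2
      sq <- rowSums(A)
      D2 <- (outer(sq, sq, `+`) - 2 * (tcrossprod(Fr) + tcrossprod(Fi))) / p
    } else {
      C <- stack_ctf_matrix(stack)[, keep, drop = FALSE]  # n x |keep| CTF rows
      A <- Fr^2 + Fi^2                     # |F_i(k)|^2
      term <- A %*% t(C^2)                 # sum_k |F_i|^2 CTF_j^2
      cross <- tcrossprod(Fr * C) + tcrossprod(Fi * C)
      D2 <- (term + t(term) - 2 * cross) / p
    }
  }
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  structure(D, kind = kind, normalized = normalize,
            resolution = resolution, mask_radius = mask_radius,
            class = "confmap_distances")
}

#' Write / read a distance matrix as CSV
#'
#' Plain headerless CSV, with the kind recorded in a `# kind:` comment line.
#' @param D matrix from [pairwise_distances()].
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distances <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", attr(D, "kind") %||% "euclidean"), con)
  utils::write.table(unclass(D), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  first <- readLines(path, n = 1)
  kind <- sub("^# kind: *", "", first)
  D <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(D) <- NULL
  structure(D, kind = kind, class = "confmap_distances")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
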