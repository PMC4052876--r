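## From embeddings to conformational results: two-class sorting with a
## cutting line in an eigenvector plane, sorting fidelity, manifold
## thickness/separation statistics, and continuous conformational
## coordinates read off the first non-trivial eigenfunction.

#' Two-class split in an eigenvector plane
#'
#' Each snapshot is represented by its coordinates in the chosen eigenvector
#' plane (default the first two non-trivial eigenvectors, psi2 and psi3).  A
#' deterministic 2-means clustering — initialized at the two points farthest
#' apart in the plane — assigns labels, and the cutting line is the
#' perpendicular bisector of the two final centroids.  Cluster 0 is the
#' larger cluster.
#'
#' @param embedding a `confmap_embedding` (or a plain coordinate matrix).
#' @param plane integer pair of coordinate columns (default `c(1, 2)`, i.e.
#'   psi2 and psi3 for a diffusion map).
#' @return object of class `sort_result`: `predicted_class` (0/1),
#'   `cutting_line` (`list(normal, offset)` with `normal . x = offset` the
#'   line), `centroids`, `plane`, `points`.
#' @export
split_two_classes <- function(embedding, plane = c(1, 2)) {
  pts <- if (inherits(embedding, "confmap_embedding")) embedding$coordinates
         else as.matrix(embedding)
  if (max(plane) > ncol(pts))
    stop_confmap("embedding has %d components; plane needs %d", ncol(pts), max(plane))
  P <- pts[, plane, drop = FALSE]
  n <- nrow(P)
  if (n < 2) stop_confmap("need at least 2 points to split")

  ## deterministic farthest-pair initialization
  sq <- rowSums(P^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(P)
  far <- arrayInd(which.max(D2), dim(D2))
  centres <- P[c(far[1], far[2]), , drop = FALSE]

  assign_lab <- function(centres) {
    d0 <- colSums((t(P) - centres[1, ])^2)
    d1 <- colSums((t(P) - centres[2, ])^2)
    as.integer(d1 < d0)
  }
  lab <- assign_lab(centres)
  for (it in seq_len(100)) {
    for (k in 0:1) if (any(lab == k))
      centres[k + 1, ] <- colMeans(P[lab == k, , drop = FALSE])
    new_lab <- assign_lab(centres)
    if (all(new_lab == lab)) break
    lab <- new_lab
  }
  if (sum(lab == 1) > sum(lab == 0)) {   # cluster 0 = larger cluster
    lab <- 1L - lab
    centres <- centres[2:1, , drop = FALSE]
  }
  v <- centres[2, ] - centres[1, ]
  nrm <- sqrt(sum(v^2))
  normal <- if (nrm > 0) v / nrm else c(1, rep(0, length(v) - 1))
  offset <- sum(normal * (centres[1, ] + centres[2, ]) / 2)
  structure(list(predicted_class = lab,
                 cutting_line = list(normal = normal, offset = offset),
                 centroids = centres, plane = plane, points = P),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("<sort_result> %d snapshots: %d / %d in clusters 0 / 1\n",
              length(x$predicted_class), sum(x$predicted_class == 0),
              sum(x$predicted_class == 1)))
  invisible(x)
}

#' Sorting fidelity
#'
#' Percentage of snapshots assigned to the correct class, maximized over the
#' two possible label permutations (cluster labels are arbitrary).
#'
#' @param predicted,truth equal-length two-class label vectors.
#' @return fidelity in percent, in \[50, 100\] for two balanced classes.
#' @export
sorting_fidelity <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop_confmap("predicted (%d) and truth (%d) lengths differ",
                 length(predicted), length(truth))
  p <- as.integer(factor(predicted)) - 1L
  t <- as.integer(factor(truth)) - 1L
  100 * max(mean(p == t), mean(p != t))
}

#' Manifold thickness and separation statistics
#'
#' Noise spreads the snapshot vectors about their conformational manifolds;
#' the spread ("thickness") of each class is quantified as the standard
#' deviation of residuals about a local line fit: for each point, the
#' residual is its distance to the principal line through its
#' `neighbourhood` nearest same-class neighbours.  The separation is the
#' smallest cross-class distance in units of the larger class width.
#'
#' @param points `n x m` coordinate matrix (e.g. leading embedding
#'   coordinates).
#' @param truth two-class label vector.
#' @param neighbourhood local fit size (default 10).
#' @return object of class `separation_stats`: `class_widths`, `min_gap`,
#'   `separation_sd`.
#' @export
manifold_separation <- function(points, truth, neighbourhood = 10) {
  points <- as.matrix(points)
  classes <- sort(unique(truth))
  if (length(classes) != 2) stop_confmap("exactly two classes expected")
  widths <- numeric(2)
  for (k in 1:2) {
    P <- points[truth == classes[k], , drop = FALSE]
    if (nrow(P) < neighbourhood + 1)
      stop_confmap("class %s has %d points; need > %d", classes[k], nrow(P),
                   neighbourhood)
    sq <- rowSums(P^2)
    D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(P)
    res <- numeric(nrow(P))
    for (i in seq_len(nrow(P))) {
      nb <- order(D2[i, ])[-1][seq_len(neighbourhood)]
      Q <- P[nb, , drop = FALSE]
      ctr <- colMeans(Q)
      dirn <- svd(sweep(Q, 2, ctr), nu = 0, nv = 1)$v[, 1]
      r <- P[i, ] - ctr
      res[i] <- sqrt(max(0, sum(r^2) - sum(r * dirn)^2))
    }
    widths[k] <- sd(res)
  }
  A <- points[truth == classes[1], , drop = FALSE]
  B <- points[truth == classes[2], , drop = FALSE]
  cross2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  min_gap <- sqrt(max(0, min(cross2)))
  structure(list(class_widths = widths, min_gap = min_gap,
                 separation_sd = min_gap / max(widths)),
            class = "separation_stats")
}

#' @export
print.separation_stats <- function(x, ...) {
  cat(sprintf("<separation_stats> widths %s, min gap %.4g => separation %.2f s.d.\n",
              paste(signif(x$class_widths, 3), collapse = " / "),
              x$min_gap, x$separation_sd))
  invisible(x)
}

#' Continuous conformational coordinate
#'
#' Reads the conformational coordinate of each snapshot off the first
#' non-trivial diffusion-map eigenfunction (psi2) and summarizes it as a
#' histogram (Freedman-Diaconis bins).  When true class labels are supplied,
#' adjacent classes (ordered by median psi2) whose 5th-95th percentile
#' intervals overlap are counted — the pairs the eigenfunction fails to
#' resolve.
#'
#' @param embedding a diffusion-map `confmap_embedding`.
#' @param truth optional per-snapshot class labels.
#' @return list with `psi2`, `histogram` (a [hist()] object), and when
#'   `truth` is given `class_order`, `class_intervals`,
#'   `n_overlapping_adjacent`.
#' @export
conformational_coordinate <- function(embedding, truth = NULL) {
  stopifnot(inherits(embedding, "confmap_embedding"))
  psi2 <- embedding$coordinates[, 1]
  h <- graphics::hist(psi2, breaks = "FD", plot = FALSE)
  out <- list(psi2 = psi2, histogram = h)
  if (!is.null(truth)) {
    classes <- sort(unique(truth))
    med <- vapply(classes, function(k) median(psi2[truth == k]), numeric(1))
    ord <- order(med)
    iv <- t(vapply(classes[ord], function(k)
      quantile(psi2[truth == k], c(0.05, 0.95), names = FALSE), numeric(2)))
    overlap <- 0L
    if (length(classes) > 1)
      for (i in seq_len(nrow(iv) - 1))
        if (iv[i, 2] >= iv[i + 1, 1]) overlap <- overlap + 1L
    out$class_order <- classes[ord]
    out$class_intervals <- iv
    out$n_overlapping_adjacent <- overlap
  }
  out
}
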