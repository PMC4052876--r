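test_that("two-means split with perpendicular-bisector cutting line", {
  # two points: each its own cluster, line bisects the segment
  sr <- split_two_classes(rbind(c(0, 0), c(2, 0)))
  expect_setequal(sr$predicted_class, c(0, 1))
  expect_equal(abs(sum(sr$cutting_line$normal * c(1, 0))), 1)
  expect_equal(sr$cutting_line$offset, 1 * sign(sr$cutting_line$normal[1]))

  # two tight clouds: every point lands on its centroid's side
  set.seed(61)
  pts <- rbind(matrix(rnorm(200, sd = 0.01), 100, 2),
               matrix(rnorm(200, 1, sd = 0.01), 100, 2))
  truth <- rep(0:1, each = 100)
  sr2 <- split_two_classes(pts)
  expect_equal(sorting_fidelity(sr2$predicted_class, truth), 100)
  # brute-force nearest-centroid oracle
  c0 <- colMeans(pts[sr2$predicted_class == 0, ])
  c1 <- colMeans(pts[sr2$predicted_class == 1, ])
  near <- as.integer(rowSums((pts - rep(c1, each = 200))^2) <
                     rowSums((pts - rep(c0, each = 200))^2))
  expect_equal(sr2$predicted_class, near)
  side <- sign(pts %*% sr2$cutting_line$normal - sr2$cutting_line$offset)
  expect_true(all(side[sr2$predicted_class == 1] > 0))
  expect_true(all(side[sr2$predicted_class == 0] < 0))

  # duplicating the dataset leaves the cutting line unchanged
  sr3 <- split_two_classes(rbind(pts, pts))
  expect_equal(sr3$cutting_line$normal, sr2$cutting_line$normal, tolerance = 1e-9)
  expect_equal(sr3$cutting_line$offset, sr2$cutting_line$offset, tolerance = 1e-9)
  expect_error(split_two_classes(pts[1, , drop = FALSE]), "at least 2")
})

test_that("sorting fidelity is permutation-invariant and exact", {
  truth <- rep(0:1, 1000)
  expect_equal(sorting_fidelity(truth, truth), 100)
  expect_equal(sorting_fidelity(1 - truth, truth), 100)
  pred <- truth; pred[17] <- 1 - pred[17]
  expect_equal(sorting_fidelity(pred, truth), 99.95)
  expect_equal(sorting_fidelity(pred, truth),
               sorting_fidelity(1 - pred, truth))
  expect_error(sorting_fidelity(truth[-1], truth), "lengths differ")
})

test_that("manifold separation statistics match a brute-force oracle", {
  # the residual noise must be small against the 10-neighbour x-spread
  # (~0.02) or the local line fit chases the noise
  set.seed(71)
  n <- 500; s <- 0.002; g <- 0.02
  # two parallel segments with bounded (truncated normal) residual noise,
  # boundary-to-boundary gap g = 10 s
  trunc_noise <- function(n) { z <- rnorm(n * 3); z <- z[abs(z) < 2][1:n]; z * s }
  A <- cbind(runif(n), trunc_noise(n))
  B <- cbind(runif(n), g + 4 * s + trunc_noise(n))
  pts <- rbind(A, B); truth <- rep(0:1, each = n)
  st <- manifold_separation(pts, truth)
  # the ratio tracks the constructed gap-to-noise scale g / s = 10; the
  # local line fit absorbs part of the perpendicular scatter, so widths sit
  # somewhat below s and the ratio above 10
  expect_gt(st$separation_sd, 10); expect_lt(st$separation_sd, 30)

  # brute-force oracle recomputes every statistic with naive loops
  gap <- min(apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2)))))
  expect_equal(st$min_gap, gap, tolerance = 1e-12)
  width_oracle <- function(P) {
    res <- vapply(seq_len(nrow(P)), function(i) {
      d <- sqrt(colSums((t(P) - P[i, ])^2))
      nb <- P[order(d)[2:11], , drop = FALSE]
      ctr <- colMeans(nb)
      v <- eigen(stats::cov(nb))$vectors[, 1]
      r <- P[i, ] - ctr
      sqrt(max(0, sum(r^2) - sum(r * v)^2))
    }, numeric(1))
    stats::sd(res)
  }
  expect_equal(st$class_widths, c(width_oracle(A), width_oracle(B)),
               tolerance = 1e-6)
  expect_equal(st$separation_sd, gap / max(st$class_widths), tolerance = 1e-12)

  # scale invariance of the ratio
  st2 <- manifold_separation(pts * 37, truth)
  expect_equal(st2$separation_sd, st$separation_sd, tolerance = 1e-9)

  # identical overlapping clouds: gap ~ 0, separation below 1
  C <- matrix(rnorm(400), 200, 2)
  st3 <- manifold_separation(rbind(C, C + 1e-4), rep(0:1, each = 200))
  expect_lt(st3$separation_sd, 1)
  expect_error(manifold_separation(pts[c(1:4, n + (1:4)), ], rep(0:1, each = 4)),
               "need >")
})

test_that("conformational coordinate reports histogram class resolution", {
  # 12 well-separated classes: no overlapping adjacent pairs
  set.seed(81)
  truth <- rep(1:12, each = 50)
  psi2 <- truth + rnorm(600, sd = 0.05)
  emb <- structure(list(coordinates = cbind(psi2, 0), eigenvalues = c(1, .9, .8),
                        method = "diffusion_map"), class = "confmap_embedding")
  cc <- conformational_coordinate(emb, truth)
  expect_equal(cc$n_overlapping_adjacent, 0L)
  expect_equal(cc$class_order, 1:12)

  # merge the last two classes into overlap
  psi2b <- psi2; psi2b[truth == 12] <- psi2b[truth == 11]
  embb <- structure(list(coordinates = cbind(psi2b, 0), eigenvalues = c(1, .9),
                         method = "diffusion_map"), class = "confmap_embedding")
  expect_equal(conformational_coordinate(embb, truth)$n_overlapping_adjacent, 1L)

  # single class: nothing to overlap
  cc1 <- conformational_coordinate(emb, rep(1, 600))
  expect_equal(cc1$n_overlapping_adjacent, 0L)
  expect_s3_class(cc$histogram, "histogram")
})
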