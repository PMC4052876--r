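test_that("diffusion map has unit top eigenvalue with constant first eigenvector", {
  set.seed(30)
  P <- matrix(rnorm(80), 40, 2)
  D <- as.matrix(stats::dist(P))
  W <- exp(-D^2 / (2 * stats::median(D)^2)); diag(W) <- 0
  emb <- diffusion_map(W, n_components = 4)
  expect_equal(emb$eigenvalues[1], 1, tolerance = 1e-9)
  expect_lt(diff(range(emb$psi1)) / max(abs(emb$psi1)), 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  expect_true(all(abs(emb$eigenvalues) <= 1 + 1e-9))
})

test_that("a three-node path graph matches the dense eigen oracle", {
  W <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  # independent oracle: literal alpha = 1 normalization and Markov eigenvalues
  d <- rowSums(W)
  W1 <- W / outer(d, d)
  M <- W1 / rowSums(W1)
  oracle <- sort(Re(eigen(M)$values), decreasing = TRUE)
  emb <- diffusion_map(W, n_components = 2)
  expect_equal(emb$eigenvalues, oracle, tolerance = 1e-12)
})

test_that("disconnected kernels error unless explicitly allowed", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1; diag(W) <- 0
  expect_error(diffusion_map(W), "connected components")
  emb <- diffusion_map(W, n_components = 3, allow_disconnected = TRUE)
  expect_equal(emb$eigenvalues[1:2], c(1, 1), tolerance = 1e-9)
  expect_lt(emb$eigenvalues[3], 1 - 1e-6)
})

test_that("embeddings are permutation-equivariant", {
  set.seed(41)
  P <- matrix(rnorm(60), 30, 2)
  D <- as.matrix(stats::dist(P))
  W <- exp(-D^2 / 2); diag(W) <- 0
  emb <- diffusion_map(W, 3)
  perm <- sample(30)
  embp <- diffusion_map(W[perm, perm], 3)
  expect_equal(embp$coordinates, emb$coordinates[perm, ], tolerance = 1e-8)
  iso <- isomap(D, k_nn = 5, n_components = 2)
  isop <- isomap(D[perm, perm], k_nn = 5, n_components = 2)
  expect_equal(isop$coordinates, iso$coordinates[perm, ], tolerance = 1e-8)
})

test_that("sparse iterative and dense eigensolvers agree", {
  # ring-graph kernel large enough to trigger the iterative path
  n <- 1300
  ang <- 2 * pi * (seq_len(n) - 1) / n
  P <- cbind(cos(ang), sin(ang))
  D <- as.matrix(stats::dist(P))
  W <- exp(-D^2 / (2 * 0.05^2)); diag(W) <- 0
  W[W < 1e-8] <- 0
  emb_sparse <- diffusion_map(W, 4)
  dense <- diffusion_map(W[seq_len(600), seq_len(600)] + 0, 4)  # dense branch
  expect_equal(emb_sparse$eigenvalues[1], 1, tolerance = 1e-9)
  # eigenvalues of the full ring from the iterative solver match a direct
  # dense solve of the same operator
  d <- rowSums(W); W1 <- W / outer(d, d); d1 <- rowSums(W1)
  S <- W1 / outer(sqrt(d1), sqrt(d1))
  oracle <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)[1:5]
  expect_equal(emb_sparse$eigenvalues, oracle, tolerance = 1e-9)
})

test_that("isomap recovers simple geometries", {
  # points on a line: first coordinate preserves the ordering (equal
  # spacing with jitter keeps the 2-NN chain connected)
  set.seed(50)
  x <- seq_len(60) / 60 + runif(60, 0, 0.004)
  D <- as.matrix(stats::dist(cbind(x, 0)))
  emb <- isomap(D, k_nn = 2, n_components = 2)
  expect_equal(abs(stats::cor(emb$coordinates[, 1], x, method = "spearman")), 1)

  # points on a circle embed as a circle (radius nearly constant)
  set.seed(52)
  ang <- 2 * pi * (seq_len(200) - 1) / 200 + rnorm(200, sd = 0.005)
  D2 <- as.matrix(stats::dist(cbind(cos(ang), sin(ang))))
  emb2 <- isomap(D2, k_nn = 4, n_components = 2)
  r <- sqrt(rowSums(emb2$coordinates[, 1:2]^2))
  expect_lt(stats::sd(r) / mean(r), 0.05)

  # duplicated points embed at the same place
  D3 <- as.matrix(stats::dist(cbind(rep(x[1:20], each = 2), 0)))
  emb3 <- isomap(D3, k_nn = 4, n_components = 1)
  expect_lt(max(abs(emb3$coordinates[seq(1, 39, 2), 1] -
                    emb3$coordinates[seq(2, 40, 2), 1])), 1e-9)
  expect_error(isomap(rbind(c(0, 1, 9, 9), c(1, 0, 9, 9), c(9, 9, 0, 1),
                            c(9, 9, 1, 0)), k_nn = 1), "disconnected")
})
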