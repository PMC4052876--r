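test_that("gate and Gaussian weighting follow the kernel definition", {
  # 4 snapshots: two co-axial pairs with the pairs pi/2 apart
  q <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0),
             t(replicate(2, confmap:::axis_angle_quat(c(0, 1, 0), pi / 2))))
  D <- matrix(2, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0                 # same view, identical snapshots
  D[3, 4] <- D[4, 3] <- sqrt(2)           # same view, distance sigma*sqrt(2)
  W <- gated_kernel(D, q, gating_params(theta_epsilon = 0.1, k_nn = 3,
                                        sigma = 1))
  W <- as.matrix(W)
  expect_equal(W[1, 2], 1)                  # exp(0)
  expect_equal(W[3, 4], exp(-1))            # exp(-(sigma sqrt 2)^2 / (2 sigma^2))
  expect_equal(W[1, 3], 0)                  # gate closed at pi/2
  expect_equal(W, t(W))
})

test_that("rows keep only the k nearest gate-open neighbours (union-symmetrized)", {
  n <- 7
  q <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)  # all same view
  set.seed(5)
  D <- as.matrix(stats::dist(matrix(rnorm(n * 2), n)))
  W <- as.matrix(gated_kernel(D, q, gating_params(1, k_nn = 2, sigma = 1)))
  picked <- lapply(seq_len(n), function(i) order(D[i, -i])[1:2])
  for (i in seq_len(n)) {
    nn <- setdiff(seq_len(n), i)[picked[[i]]]
    for (j in setdiff(seq_len(n), c(i, nn)))
      if (W[i, j] > 0)                     # only allowed via union with row j
        expect_true(i %in% setdiff(seq_len(n), j)[picked[[j]]])
  }
  expect_true(all(rowSums(W > 0) >= 2))
})

test_that("an isolated snapshot after gating raises an informative error", {
  q <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0),
             confmap:::axis_angle_quat(c(0, 1, 0), pi / 2))
  D <- matrix(1, 3, 3); diag(D) <- 0
  expect_error(gated_kernel(D, q, gating_params(0.1, 1, sigma = 1)),
               "no gate-open neighbour")
  expect_error(gated_kernel(D, NULL, gating_params(0.1, 1, sigma = 1)),
               "one orientation per snapshot")
})

test_that("automatic bandwidth lands on the pairwise-distance scale", {
  # equal distances d: the log S(sigma) transition is centred on d
  n <- 40
  for (d in c(0.5, 3, 40)) {
    D <- matrix(d, n, n); diag(D) <- 0
    sig <- select_sigma(D)
    expect_gt(sig, d / 2); expect_lt(sig, d * 2)
  }
  # scale equivariance within grid resolution
  set.seed(8)
  D <- as.matrix(stats::dist(matrix(rnorm(60), 30)))
  expect_equal(select_sigma(D * 7) / select_sigma(D), 7, tolerance = 0.1)
  # two well-separated scales: sigma falls between them
  n <- 30
  block <- matrix(0.98, n / 2, n / 2)
  D2 <- rbind(cbind(block, matrix(100, n / 2, n / 2)),
              cbind(matrix(100, n / 2, n / 2), block))
  D2 <- D2 * (1 + 0.02 * as.matrix(stats::dist(matrix(rnorm(n), n)))) / 1
  diag(D2) <- 0; D2 <- (D2 + t(D2)) / 2
  s2 <- select_sigma(D2)
  expect_gt(s2, 0.5); expect_lt(s2, 100)
  expect_error(select_sigma(matrix(0, 4, 4)), "degenerate")
})

test_that("gating parameter validation", {
  expect_error(gating_params(theta_epsilon = 0), "theta_epsilon")
  expect_error(gating_params(0.1, k_nn = 0), "k_nn")
})

test_that("the SO(3) misorientation gate also sees in-plane rotation", {
  # two snapshots along the same viewing axis but spun in-plane by 0.5 rad:
  # open under the viewing-axis gate, closed under the misorientation gate
  q <- rbind(c(1, 0, 0, 0), confmap:::axis_angle_quat(c(0, 0, 1), 0.5),
             confmap:::axis_angle_quat(c(0, 0, 1), 0.52),
             confmap:::axis_angle_quat(c(0, 1, 0), 0.05))
  D <- matrix(1, 4, 4); diag(D) <- 0
  Wax <- as.matrix(gated_kernel(D, q, gating_params(0.1, 2, sigma = 1)))
  expect_gt(Wax[1, 2], 0)
  Wso <- as.matrix(gated_kernel(D, q, gating_params(0.1, 2, sigma = 1,
                                                    delta_theta = "so3")))
  expect_equal(Wso[1, 2], 0)               # in-plane spin closes the gate
  expect_gt(Wso[2, 3], 0)                  # small true misorientation stays open
  expect_gt(Wso[1, 4], 0)
})
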