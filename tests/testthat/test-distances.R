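test_that("euclidean distance matches a brute-force oracle", {
  a <- rand_image(8, 1); b <- rand_image(8, 2)
  expect_equal(euclidean_distance(a, a), 0)
  b1 <- a; b1[3, 5] <- b1[3, 5] + 3
  expect_equal(euclidean_distance(a, b1), 3)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(euclidean_distance(a, b), sqrt(acc), tolerance = 1e-12)
  expect_error(euclidean_distance(a, rand_image(6, 1)), "shapes differ")
})

test_that("double-filtered distance vanishes for snapshots differing only in defocus", {
  P <- normalize_snapshot(project(make_phantom(tiny_spec(), 0), c(1, 0, 0, 0)))
  set.seed(40)
  for (r in 1:5) {
    dz <- runif(2, 1.5, 2.5)
    c1 <- ctf_function(ctf_params(defocus = dz[1], pixel_size = 10), 32)
    c2 <- ctf_function(ctf_params(defocus = dz[2], pixel_size = 10), 32)
    I1 <- apply_ctf(P, c1); I2 <- apply_ctf(P, c2)
    expect_lt(double_filtered_distance(I1, c1, I2, c2) / sqrt(sum(P^2)), 1e-6)
  }
  img <- rand_image(8, 5); flt <- ctf_function(ctf_params(2, pixel_size = 5), 8)
  expect_equal(double_filtered_distance(img, flt, img, flt), 0, tolerance = 1e-12)
})

test_that("Fourier-space double filtering equals the real-space convolution oracle", {
  # Parseval equivalence on 100 random instances.  Filters must be the
  # transforms of real point-spread functions, i.e. Hermitian-symmetric:
  # build each from an inversion-symmetrized random PSF.
  set.seed(77)
  conj_idx <- c(1, 8:2)
  rand_ctf <- function() {
    s <- matrix(rnorm(64), 8, 8)
    s <- (s + s[conj_idx, conj_idx]) / 2
    Re(stats::fft(s))
  }
  for (r in 1:100) {
    Ii <- matrix(rnorm(64), 8, 8); Ij <- matrix(rnorm(64), 8, 8)
    ci <- rand_ctf(); cj <- rand_ctf()
    direct <- sqrt(sum((circ_conv(psf_of(cj), Ii) - circ_conv(psf_of(ci), Ij))^2))
    fourier <- double_filtered_distance(Ii, ci, Ij, cj)
    expect_equal(fourier, direct, tolerance = 1e-9)
  }
})

test_that("pairwise distance matrices are symmetric, zero-diagonal and equivariant", {
  spec <- tiny_spec()
  stack <- forge_dataset(spec, 6, seed = 3)
  D <- pairwise_distances(stack, "double_filtered")
  expect_equal(unclass(D), t(unclass(D)))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  expect_equal(length(unique(round(D[upper.tri(D)], 9))), 15)

  # permuting snapshots permutes rows and columns consistently
  perm <- c(4, 1, 6, 2, 5, 3)
  stackp <- snapshot_stack(stack$images[perm, ], stack$metadata[perm, ],
                           pixel_size = stack$pixel_size, imaging = "cryoem",
                           ctf = stack$ctf, side = stack$side)
  Dp <- pairwise_distances(stackp, "double_filtered")
  expect_equal(matrix(Dp, 6), matrix(D, 6)[perm, perm], tolerance = 1e-9)
})

test_that("with an identity-like CTF the double-filtered matrix is Euclidean", {
  # A = 1, Cs = 0, defocus 0 gives CTF = -1 everywhere: both filters flip
  # sign, norms are unchanged, and the matrix must equal the plain one
  set.seed(12)
  X <- matrix(rnorm(5 * 16 * 16), 5)
  st <- matrix_stack(X, 16, imaging = "cryoem", defocus = rep(0, 5),
                     ctf = list(cs = 0, voltage = 300, amplitude_contrast = 1))
  D2f <- pairwise_distances(st, "double_filtered")
  Deu <- pairwise_distances(st, "euclidean")
  expect_equal(matrix(D2f, 5), matrix(Deu, 5), tolerance = 1e-9)
})

test_that("double-filtered distances require CTF metadata", {
  spec <- tiny_spec()
  stack <- forge_dataset(spec, 4, imaging = "diffraction", seed = 5)
  expect_error(pairwise_distances(stack, "double_filtered"), "defocus")
})

test_that("a resolution cutoff restricts the comparison to the low band", {
  set.seed(21)
  X <- matrix(rnorm(4 * 32 * 32), 4)
  st <- matrix_stack(X, 32, pixel_size = 5)
  # oracle: low-pass each image by zeroing |k| > 1/res, then plain Euclidean
  res <- 20
  keep <- confmap:::freq_radius(32, 5) <= 1 / res
  lp <- t(apply(X, 1, function(v) {
    f <- stats::fft(matrix(v, 32, 32)) * keep
    as.vector(Re(stats::fft(f, inverse = TRUE)) / 1024)
  }))
  stlp <- matrix_stack(lp, 32, pixel_size = 5)
  Dlow <- pairwise_distances(st, "euclidean", normalize = FALSE,
                             resolution = res)
  Dora <- pairwise_distances(stlp, "euclidean", normalize = FALSE)
  expect_equal(matrix(Dlow, 4), matrix(Dora, 4), tolerance = 1e-9)
  expect_error(pairwise_distances(st, "euclidean", resolution = 3),
               "Nyquist")
})

test_that("distance matrices round-trip through CSV", {
  stack <- forge_dataset(tiny_spec(), 4, seed = 9)
  D <- pairwise_distances(stack, "euclidean")
  f <- tempfile(fileext = ".csv")
  write_distances(D, f)
  D2 <- read_distances(f)
  expect_equal(matrix(D2, nrow(D2)), matrix(D, nrow(D)), tolerance = 1e-12)
  expect_equal(attr(D2, "kind"), "euclidean")
})
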