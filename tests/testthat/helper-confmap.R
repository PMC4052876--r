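# Shared fixture builders.  All fixtures are generated in code; sizes are
# kept small so each unit file runs in seconds.

# a cheap 32^3 phantom family (10 A voxels, same blob layout)
tiny_spec <- function(mode = "extra_domain_pair", ...) {
  conformation_spec(mode, grid_size = 32, voxel_size = 10, ...)
}

# single-blob spherical phantom (exact rotational symmetry)
sphere_spec <- function(grid_size = 32, voxel_size = 10) {
  conformation_spec("discrete_pair", grid_size = grid_size,
                    voxel_size = voxel_size, motion_amplitude = 1,
                    blobs = data.frame(x = 0, y = 0, z = 0, sigma = 30,
                                       weight = 1, group = "core"))
}

# deterministic pseudo-random image
rand_image <- function(side, seed = 1) {
  set.seed(seed)
  matrix(rnorm(side * side), side, side)
}

# brute-force real-space circular convolution (independent oracle)
circ_conv <- function(psf, img) {
  n <- nrow(img)
  out <- matrix(0, n, n)
  for (a in 1:n) for (b in 1:n) {
    s <- 0
    for (u in 1:n) for (v in 1:n) {
      s <- s + psf[u, v] * img[((a - u) %% n) + 1, ((b - v) %% n) + 1]
    }
    out[a, b] <- s
  }
  out
}

# real-space point-spread function of a Fourier-space filter
psf_of <- function(ctf) Re(stats::fft(ctf, inverse = TRUE)) / length(ctf)

# minimal stack wrapper around a pixel matrix
matrix_stack <- function(X, side, pixel_size = 5, imaging = "diffraction",
                         defocus = NULL, ctf = NULL, class = NULL, quats = NULL) {
  n <- nrow(X)
  if (is.null(quats)) quats <- sample_orientations(n, "uniform_so3", seed = 99)
  md <- data.frame(snapshot_id = seq_len(n) - 1L,
                   qw = quats[, 1], qx = quats[, 2], qy = quats[, 3],
                   qz = quats[, 4],
                   defocus_um = if (is.null(defocus)) NA_real_ else defocus,
                   true_class = if (is.null(class)) 0L else class,
                   conf_coord = 0)
  snapshot_stack(X, md, pixel_size = pixel_size, imaging = imaging,
                 ctf = ctf, side = side)
}
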