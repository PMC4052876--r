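## The snapshot forge: end-to-end synthetic dataset generation, composing
## phantom -> orientations -> projection -> CTF -> noise (cryo-EM mode) or
## phantom -> orientations -> projection -> |FT|^2 -> Poisson (diffraction).

#' Snapshot stack container
#'
#' A set of n equally shaped 2D snapshots with per-snapshot metadata.
#'
#' @param images `side x side x n` array (or `n x p` matrix with `side`
#'   given), intensities or photon counts.
#' @param metadata data frame with one row per snapshot; columns
#'   `snapshot_id, qw, qx, qy, qz, defocus_um, true_class, conf_coord`
#'   (defocus is `NA` for diffraction stacks).
#' @param pixel_size pixel size in Angstrom.
#' @param imaging `"cryoem"` or `"diffraction"`.
#' @param ctf list of shared microscope constants (`cs`, `voltage`,
#'   `amplitude_contrast`) for cryo-EM stacks.
#' @param side image side length (needed when `images` is a flat matrix).
#' @return object of class `snapshot_stack`.
#' @export
snapshot_stack <- function(images, metadata, pixel_size = 5,
                           imaging = c("cryoem", "diffraction"),
                           ctf = NULL, side = NULL) {
  imaging <- match.arg(imaging)
  if (length(dim(images)) == 3) {
    side <- dim(images)[1]
    stopifnot(dim(images)[2] == side)
    n <- dim(images)[3]
    flat <- t(matrix(images, side * side, n))
  } else {
    if (is.null(side)) stop_confmap("side must be given for flat image matrices")
    flat <- images
    n <- nrow(flat)
  }
  if (nrow(metadata) != n)
    stop_confmap("metadata has %d rows for %d snapshots", nrow(metadata), n)
  structure(list(images = flat, side = side, n = n, metadata = metadata,
                 pixel_size = pixel_size, imaging = imaging, ctf = ctf),
            class = "snapshot_stack")
}

## n x p pixel matrix view of a stack.
stack_matrix <- function(stack) {
  stopifnot(inherits(stack, "snapshot_stack"))
  stack$images
}

stack_image <- function(stack, i) {
  matrix(stack$images[i, ], stack$side, stack$side)
}

## n x p matrix of per-snapshot CTF filters (flattened frequency grids).
stack_ctf_matrix <- function(stack) {
  md <- stack$metadata
  if (is.null(md$defocus_um) || anyNA(md$defocus_um))
    stop_confmap("double-filtered distances need per-snapshot defocus metadata")
  ctf <- stack$ctf %||% list(cs = 2, voltage = 300, amplitude_contrast = 0.07)
  ## cache identical-defocus rows (constant-defocus stacks)
  uniq <- !duplicated(md$defocus_um)
  filt <- matrix(0, stack$n, stack$side^2)
  cache <- list()
  for (i in seq_len(stack$n)) {
    key <- sprintf("%.9g", md$defocus_um[i])
    if (is.null(cache[[key]])) {
      p <- ctf_params(defocus = md$defocus_um[i], cs = ctf$cs,
                      voltage = ctf$voltage,
                      amplitude_contrast = ctf$amplitude_contrast,
                      pixel_size = stack$pixel_size)
      cache[[key]] <- as.vector(ctf_function(p, stack$side))
    }
    filt[i, ] <- cache[[key]]
  }
  filt
}

#' @export
print.snapshot_stack <- function(x, ...) {
  cat(sprintf("<snapshot_stack> %d %s snapshots, %dx%d px at %g A/px\n",
              x$n, x$imaging, x$side, x$side, x$pixel_size))
  if (!is.null(x$metadata$true_class))
    print(table(class_label = x$metadata$true_class))
  invisible(x)
}

#' Forge a complete synthetic dataset
#'
#' Generates `n` snapshots from a [conformation_spec()]: renders the phantom
#' conformations, samples orientations, projects, and applies the imaging
#' model (CTF + calibrated noise for `"cryoem"`; squared Fourier modulus +
#' Poisson photon sampling for `"diffraction"`).
#'
#' For the two pair modes, class labels 0/1 are balanced unless
#' `mixing_fraction` is given.  For `continuous_path`,
#' `spec$n_conformations` equally spaced coordinates are used and
#' `true_class` holds the conformation index (0-based).  Cryo-EM snapshots
#' are generated with canonically in-plane-aligned orientations by default
#' (uniform viewing directions, no in-plane spin), the frame in which
#' orientation-gated comparisons of snapshots with known orientations are
#' made.
#'
#' @param spec a [conformation_spec()].
#' @param n number of snapshots.
#' @param imaging `"cryoem"` or `"diffraction"`.
#' @param defocus_range length-2 range in micrometres (cryo-EM); a length-1
#'   value holds defocus constant.
#' @param noise a [noise_spec()] (cryo-EM).
#' @param mean_photons_per_pixel Poisson rate (diffraction).
#' @param orientation_mode `"uniform_so3"`, `"uniform_axes"` (uniform viewing
#'   directions, canonical in-plane alignment) or `"single_axis"`.
#' @param axis rotation axis for `single_axis`.
#' @param mixing_fraction fraction of snapshots in class 1 (pair modes).
#' @param ctf shared microscope constants (list with `cs`, `voltage`,
#'   `amplitude_contrast`).
#' @param seed master seed; all randomness (orientations, defocus, noise,
#'   photons) derives from it.
#' @return a [snapshot_stack()].
#' @export
forge_dataset <- function(spec, n,
                          imaging = c("cryoem", "diffraction"),
                          defocus_range = c(1.5, 2.5),
                          noise = noise_spec(-12, 0.5),
                          mean_photons_per_pixel = 0.04,
                          orientation_mode = NULL,
                          axis = c(0, 0, 1),
                          mixing_fraction = 0.5,
                          ctf = list(cs = 2, voltage = 300,
                                     amplitude_contrast = 0.07),
                          seed = 1L) {
  imaging <- match.arg(imaging)
  stopifnot(inherits(spec, "conformation_spec"))
  seeds <- child_seeds(seed, 4)
  if (is.null(orientation_mode))
    orientation_mode <- if (imaging == "cryoem") "uniform_axes" else "uniform_so3"

  ## conformational coordinates and class labels
  if (spec$mode == "continuous_path") {
    k <- spec$n_conformations
    coords <- seq(0, 1, length.out = k)
    cls <- rep(seq_len(k) - 1L, length.out = n)
    cls <- sort(cls)
    conf <- coords[cls + 1L]
  } else {
    n1 <- round(n * mixing_fraction)
    cls <- rep_len(c(0L, 1L), n)          # interleaved, balanced by default
    if (sum(cls) != n1) cls <- c(rep(1L, n1), rep(0L, n - n1))
    conf <- as.numeric(cls)
  }

  ## orientations
  if (orientation_mode == "single_axis" && spec$mode == "continuous_path" &&
      n %% spec$n_conformations == 0) {
    m <- n / spec$n_conformations
    per <- sample_orientations(m, "single_axis", axis = axis, seed = seeds[1])
    q <- per[rep(seq_len(m), times = spec$n_conformations), , drop = FALSE]
  } else if (orientation_mode == "uniform_axes") {
    q <- sample_aligned_orientations(n, seed = seeds[1])
  } else {
    q <- sample_orientations(n, orientation_mode, axis = axis, seed = seeds[1])
  }

  ## per-snapshot defocus
  defocus <- if (imaging == "cryoem") {
    set.seed(seeds[2])
    if (length(defocus_range) == 1) rep(defocus_range, n)
    else runif(n, defocus_range[1], defocus_range[2])
  } else rep(NA_real_, n)

  ## render phantoms once per distinct coordinate (analytic projections only)
  phantoms <- lapply(unique(conf), function(cc)
    make_phantom(spec, cc, build_grid = FALSE))
  names(phantoms) <- sprintf("%.9g", unique(conf))

  side <- spec$grid_size
  images <- matrix(0, n, side * side)
  nseeds <- child_seeds(seeds[3], n)
  ctf_cache <- list()
  for (i in seq_len(n)) {
    ph <- phantoms[[sprintf("%.9g", conf[i])]]
    if (imaging == "cryoem") {
      img <- project(ph, q[i, ])
      key <- sprintf("%.9g", defocus[i])
      if (is.null(ctf_cache[[key]]))
        ctf_cache[[key]] <- ctf_function(
          ctf_params(defocus = defocus[i], cs = ctf$cs, voltage = ctf$voltage,
                     amplitude_contrast = ctf$amplitude_contrast,
                     pixel_size = spec$voxel_size), side)
      img <- apply_ctf(img, ctf_cache[[key]])
      img <- add_noise(img, noise, seed = nseeds[i])
    } else {
      img <- diffraction_pattern(ph, q[i, ], mean_photons_per_pixel,
                                 seed = nseeds[i])
    }
    images[i, ] <- img
  }

  metadata <- data.frame(
    snapshot_id = seq_len(n) - 1L,
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
    defocus_um = defocus, true_class = cls, conf_coord = conf
  )
  snapshot_stack(images, metadata, pixel_size = spec$voxel_size,
                 imaging = imaging, ctf = ctf, side = side)
}

## Uniform viewing directions with canonical (minimal-rotation) in-plane
## alignment: the quaternion is the shortest rotation taking the viewing
## axis onto the laboratory z axis, so there is no in-plane spin component.
sample_aligned_orientations <- function(n, seed = 1L) {
  set.seed(as.integer(seed))
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  q <- matrix(0, n, 4)
  for (i in seq_len(n)) {
    v <- u[i, ]
    c_th <- v[3]                      # cos(angle to z)
    ax <- c(v[2], -v[1], 0)           # v x e_z
    nrm <- sqrt(sum(ax^2))
    q[i, ] <- if (nrm < 1e-12) {
      if (c_th > 0) c(1, 0, 0, 0) else c(0, 1, 0, 0)   # flip about x
    } else axis_angle_quat(ax / nrm, acos(max(-1, min(1, c_th))))
  }
  colnames(q) <- c("qw", "qx", "qy", "qz")
  q
}

#' Write a snapshot stack to disk
#'
#' Writes `<basename>.mrcs` (MRC mode-2 stack) and `<basename>_meta.csv`
#' (per-snapshot orientation quaternion, defocus, class, conformational
#' coordinate), plus `<basename>_stack.yaml` recording pixel size, imaging
#' mode and microscope constants.
#'
#' @param stack a [snapshot_stack()].
#' @param dir output directory (created if needed).
#' @param basename file stem, default `"stack"`.
#' @return the `.mrcs` path, invisibly.
#' @export
write_snapshot_stack <- function(stack, dir, basename = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- array(t(stack$images), dim = c(stack$side, stack$side, stack$n))
  mrc <- file.path(dir, paste0(basename, ".mrcs"))
  write_mrc(arr, mrc, pixel_size = stack$pixel_size)
  write.csv(stack$metadata, file.path(dir, paste0(basename, "_meta.csv")),
            row.names = FALSE)
  yaml::write_yaml(list(pixel_size = stack$pixel_size, imaging = stack$imaging,
                        ctf = stack$ctf),
                   file.path(dir, paste0(basename, "_stack.yaml")))
  invisible(mrc)
}

#' Read a snapshot stack written by [write_snapshot_stack()]
#'
#' @param dir directory containing the stack files.
#' @param basename file stem, default `"stack"`.
#' @return a [snapshot_stack()].
#' @export
read_snapshot_stack <- function(dir, basename = "stack") {
  mrc <- read_mrc(file.path(dir, paste0(basename, ".mrcs")))
  meta_path <- file.path(dir, paste0(basename, "_meta.csv"))
  if (!file.exists(meta_path)) stop_confmap("metadata sidecar not found: %s", meta_path)
  md <- read.csv(meta_path)
  need <- c("snapshot_id", "qw", "qx", "qy", "qz", "true_class", "conf_coord")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop_confmap("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  info_path <- file.path(dir, paste0(basename, "_stack.yaml"))
  info <- if (file.exists(info_path)) yaml::read_yaml(info_path) else list()
  snapshot_stack(mrc$images, md,
                 pixel_size = info$pixel_size %||% mrc$pixel_size,
                 imaging = info$imaging %||% "cryoem",
                 ctf = info$ctf)
}
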