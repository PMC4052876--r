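## End-to-end orchestration: forge or load a stack, compute distances, build
## the (optionally gated) kernel, embed, and run the conformational analysis,
## with every parameter logged to a JSON report and the resolved
## configuration written beside the outputs.

#' Effective particle diameter of a phantom family
#'
#' Largest extent (centre distance + 2 sigma, doubled) over the blobs of the
#' two extreme conformations; used to convert a resolution into a Shannon
#' angle.
#'
#' @param spec a [conformation_spec()].
#' @return diameter in Angstrom.
#' @export
particle_diameter <- function(spec) {
  ext <- function(cc) {
    b <- pose_blobs(spec, cc)
    max(sqrt(b$x^2 + b$y^2 + b$z^2) + 2 * b$sigma)
  }
  2 * max(ext(0), ext(1))
}

#' Default analysis configuration
#'
#' @return nested list of all pipeline parameters; any subset can be
#'   overridden via the `config` argument of [run_pipeline()].
#' @export
default_config <- function() {
  list(
    forge = list(mode = "extra_domain_pair", n = 1000, imaging = "cryoem",
                 grid_size = 64, voxel_size = 5, motion_amplitude = 40,
                 n_conformations = 2,
                 defocus = c(1.5, 2.5), snr_db = -12, background_fraction = 0.5,
                 mean_photons_per_pixel = 0.04, orientation_mode = NULL),
    input = NULL,                     # list(dir=, basename=) to load instead
    ## kind NULL = by imaging mode; resolution "auto" = twice the Nyquist
    ## resolution (the blob-phantom information limit); normalize "auto" =
    ## variance-normalize images, keep photon counts on their natural scale;
    ## mask "auto" = soft particle-support mask for images, none for
    ## (delocalized) diffraction patterns
    distances = list(kind = NULL, normalize = "auto", resolution = "auto",
                     mask = "auto"),
    kernel = list(theta_epsilon = "two_shannon", k_nn = 3, sigma = "auto",
                  delta_theta = "viewing_axis"),
    embedding = list(method = "diffusion_map", n_components = 5, alpha = 1),
    analysis = list(task = "sort", plane = c(1, 2), n_coords = 3,
                    neighbourhood = 10),
    output = list(dir = NULL, plots = TRUE),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full conformational-analysis pipeline
#'
#' Orchestrates forge/load, normalization, pairwise distances, the
#' orientation-gated kernel, the spectral embedding, and either two-class
#' sorting (`analysis$task = "sort"`) or the continuous conformational
#' coordinate (`"continuum"`).  Fully seeded and deterministic; with
#' `output$dir` set, the report JSON, resolved config, embedding CSV and
#' diagnostic PNGs are written there.
#'
#' @param config nested list overriding [default_config()], or a path to a
#'   YAML file with the same structure.
#' @param seed optional seed overriding `config$seed`.
#' @return the report, an object of class `confmap_report` (a list).
#' @export
run_pipeline <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  spec <- NULL
  if (is.null(cfg$input)) {
    f <- cfg$forge
    spec <- conformation_spec(mode = f$mode, grid_size = f$grid_size,
                              voxel_size = f$voxel_size,
                              motion_amplitude = f$motion_amplitude,
                              n_conformations = max(2, f$n_conformations))
    stack <- forge_dataset(spec, n = f$n, imaging = f$imaging,
                           defocus_range = f$defocus,
                           noise = noise_spec(f$snr_db, f$background_fraction),
                           mean_photons_per_pixel = f$mean_photons_per_pixel,
                           orientation_mode = f$orientation_mode,
                           seed = cfg$seed)
  } else {
    stack <- read_snapshot_stack(cfg$input$dir,
                                 cfg$input$basename %||% "stack")
  }

  kind <- cfg$distances$kind %||%
    if (stack$imaging == "cryoem") "double_filtered" else "euclidean"
  res <- cfg$distances$resolution
  if (identical(res, "auto")) res <- 4 * stack$pixel_size
  nrm <- cfg$distances$normalize
  if (identical(nrm, "auto")) nrm <- stack$imaging == "cryoem"
  mask <- cfg$distances$mask %||% "auto"
  if (identical(mask, "auto"))
    mask <- if (stack$imaging == "cryoem" && !is.null(spec))
      particle_diameter(spec) / 2 + (res %||% 2 * stack$pixel_size) else NULL
  D <- pairwise_distances(stack, kind = kind, normalize = isTRUE(nrm),
                          resolution = res, mask_radius = mask)
  cfg$distances$resolution <- res
  cfg$distances$normalize <- nrm
  cfg$distances$mask <- mask

  theta <- cfg$kernel$theta_epsilon
  if (identical(theta, "two_shannon")) {
    if (is.null(spec))
      stop_confmap("theta_epsilon = 'two_shannon' needs a forged phantom; give a numeric gate")
    theta <- 2 * shannon_angle(particle_diameter(spec),
                               res %||% (2 * stack$pixel_size))
  }
  if (is.character(theta) && tolower(theta) %in% c("inf", "infinite")) theta <- Inf

  sigma_used <- NULL
  if (cfg$embedding$method == "isomap") {
    emb <- isomap(D, k_nn = cfg$kernel$k_nn,
                  n_components = cfg$embedding$n_components)
  } else {
    quats <- as.matrix(stack$metadata[, c("qw", "qx", "qy", "qz")])
    gp <- gating_params(theta_epsilon = theta, k_nn = cfg$kernel$k_nn,
                        sigma = cfg$kernel$sigma,
                        delta_theta = cfg$kernel$delta_theta)
    W <- gated_kernel(D, quats, gp)
    sigma_used <- attr(W, "sigma")
    emb <- diffusion_map(W, n_components = cfg$embedding$n_components,
                         alpha = cfg$embedding$alpha)
  }

  cfg$kernel$theta_epsilon <- theta
  report <- list(parameters = cfg, sigma = sigma_used,
                 n_snapshots = stack$n, distance_kind = kind,
                 eigenvalues = emb$eigenvalues)

  truth <- stack$metadata$true_class
  if (cfg$analysis$task == "sort") {
    sr <- split_two_classes(emb, plane = cfg$analysis$plane)
    report$fidelity <- sorting_fidelity(sr$predicted_class, truth)
    report$cutting_line <- sr$cutting_line
    m <- min(cfg$analysis$n_coords, ncol(emb$coordinates))
    sep <- manifold_separation(emb$coordinates[, seq_len(m), drop = FALSE],
                               truth,
                               neighbourhood = cfg$analysis$neighbourhood)
    report$separation_sd <- sep$separation_sd
    report$class_widths <- sep$class_widths
    report$min_gap <- sep$min_gap
  } else {
    cc <- conformational_coordinate(emb, truth)
    report$n_overlapping_adjacent <- cc$n_overlapping_adjacent
    report$spearman_psi2_vs_coord <-
      cor(cc$psi2, stack$metadata$conf_coord, method = "spearman")
  }

  class(report) <- "confmap_report"
  if (!is.null(cfg$output$dir))
    write_report(report, emb, stack, cfg, sr = if (cfg$analysis$task == "sort")
                 sr else NULL)
  report
}

write_report <- function(report, emb, stack, cfg, sr = NULL) {
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output$dir, f)
  jsonlite::write_json(unclass_deep(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  yaml::write_yaml(cfg, out("config_resolved.yaml"))
  write_embedding(emb, out("embedding.csv"))
  if (isTRUE(cfg$output$plots)) {
    truth <- stack$metadata$true_class
    grDevices::png(out("eigenvector_plane.png"), width = 700, height = 700)
    plot(emb$coordinates[, cfg$analysis$plane %||% c(1, 2)],
         col = truth + 2, pch = 20, xlab = "psi2", ylab = "psi3",
         main = "snapshots in the (psi2, psi3) plane")
    if (!is.null(sr)) {
      nl <- sr$cutting_line$normal; off <- sr$cutting_line$offset
      if (abs(nl[2]) > 1e-12) graphics::abline(a = off / nl[2], b = -nl[1] / nl[2])
      else graphics::abline(v = off / nl[1])
    }
    grDevices::dev.off()
    grDevices::png(out("psi2_histogram.png"), width = 700, height = 500)
    graphics::hist(emb$coordinates[, 1], breaks = "FD", xlab = "psi2",
                   main = "first non-trivial eigenfunction")
    grDevices::dev.off()
  }
  invisible(report)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' @export
print.confmap_report <- function(x, ...) {
  cat(sprintf("<confmap_report> %d snapshots, %s distances\n",
              x$n_snapshots, x$distance_kind))
  if (!is.null(x$fidelity))
    cat(sprintf("  sorting fidelity: %.2f%%\n", x$fidelity))
  if (!is.null(x$separation_sd))
    cat(sprintf("  manifold separation: %.2f s.d.\n", x$separation_sd))
  if (!is.null(x$spearman_psi2_vs_coord))
    cat(sprintf("  Spearman(psi2, conformational coordinate): %.3f\n",
                x$spearman_psi2_vs_coord))
  if (!is.null(x$n_overlapping_adjacent))
    cat(sprintf("  overlapping adjacent class pairs: %d\n",
                x$n_overlapping_adjacent))
  invisible(x)
}
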