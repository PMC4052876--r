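#' Noise specification
#'
#' Background plus shot-like noise at a stated signal-to-noise ratio.  The
#' SNR is the ratio of signal variance to total noise variance, in decibels
#' (`10*log10`); -12 dB is 0.063 on a linear scale, typical of experimental
#' cryo-EM snapshots.
#'
#' @param snr_db signal-to-noise ratio in dB.
#' @param background_fraction fraction of the noise variance carried by the
#'   Gaussian background; the remainder is signal-dependent (shot-like).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(snr_db = -12, background_fraction = 0.5) {
  if (!is.finite(snr_db)) stop_confmap("snr_db must be finite")
  if (background_fraction < 0 || background_fraction > 1)
    stop_confmap("background_fraction must lie in [0, 1]")
  structure(list(snr_db = snr_db, background_fraction = background_fraction),
            class = "noise_spec")
}

#' Add calibrated background and shot noise
#'
#' Adds zero-mean noise calibrated so that `var(image) / var(noise)` equals
#' the linear SNR `10^(snr_db/10)`.  A `background_fraction` share of the
#' noise variance is stationary Gaussian background; the remainder is
#' shot-like, i.e. Gaussian with local variance proportional to `|image|`
#' (rescaled so its mean variance matches the share).
#'
#' @param image numeric matrix.
#' @param noise a [noise_spec()].
#' @param seed integer seed (reproducible).
#' @return matrix of the same shape.
#' @export
add_noise <- function(image, noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_spec"))
  sig_var <- var(as.vector(image))
  if (sig_var <= 0)
    stop_confmap("cannot calibrate noise for a constant image (zero signal variance)")
  noise_var <- sig_var / 10^(noise$snr_db / 10)
  set.seed(as.integer(seed))
  bg_sd <- sqrt(noise$background_fraction * noise_var)
  shot_share <- (1 - noise$background_fraction) * noise_var
  local_var <- abs(image)
  m <- mean(local_var)
  shot_sd <- if (m > 0 && shot_share > 0) sqrt(shot_share * local_var / m) else 0
  image +
    matrix(rnorm(length(image), sd = bg_sd), nrow = nrow(image)) +
    matrix(rnorm(length(image)), nrow = nrow(image)) * shot_sd
}

#' Variance-normalize a snapshot
#'
#' Shifts and scales a snapshot to mean 0, variance 1 — the standard display
#' and pre-distance normalization for low-dose images.
#'
#' @param image numeric matrix (non-constant).
#' @return matrix of the same shape with mean 0 and unit variance.
#' @export
normalize_snapshot <- function(image) {
  s <- sd(as.vector(image))
  if (!is.finite(s) || s == 0) stop_confmap("cannot normalize a constant image")
  (image - mean(image)) / s
}
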