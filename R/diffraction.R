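#' Simulate a photon-sparse diffraction pattern
#'
#' Far-field single-particle diffraction in the flat-Ewald-sphere
#' approximation: the noise-free intensity is the squared modulus of the 2D
#' Fourier transform of the parallel projection of the particle, rescaled so
#' its mean over detector pixels equals `mean_photons_per_pixel`, then
#' Poisson-sampled per pixel (shot noise).
#'
#' @param phantom a [make_phantom()] object.
#' @param orientation unit quaternion.
#' @param mean_photons_per_pixel requested mean photon count per detector
#'   pixel (0.04 is a typical sparse single-particle level).
#' @param seed integer seed.
#' @param poisson if `FALSE`, return the noise-free intensity (photon rate).
#' @return integer photon-count matrix (or a rate matrix when
#'   `poisson = FALSE`), frequency layout as [stats::fft()].
#' @export
diffraction_pattern <- function(phantom, orientation, mean_photons_per_pixel,
                                seed = 1L, poisson = TRUE) {
  if (mean_photons_per_pixel < 0) stop_confmap("photon rate must be >= 0")
  proj <- project(phantom, orientation)
  intens <- Mod(fft2(proj))^2
  m <- mean(intens)
  rate <- if (m > 0) intens * (mean_photons_per_pixel / m)
          else intens * 0
  if (!poisson) return(rate)
  set.seed(as.integer(seed))
  matrix(rpois(length(rate), lambda = as.vector(rate)), nrow = nrow(rate))
}
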