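## Contrast transfer function of a weak-phase-object microscope: defocus and
## spherical aberration, with an amplitude-contrast fraction; no astigmatism
## and no envelope.  Sign convention: positive defocus = underfocus, and
## CTF(k) = -[sqrt(1 - A^2) sin(gamma) + A cos(gamma)] with
## gamma(k) = pi * lambda * dz * k^2 - (pi/2) * Cs * lambda^3 * k^4,
## so that CTF(0) = -A and low frequencies of a dense object come out dark.

#' Microscope parameters
#'
#' @param defocus defocus in micrometres (positive = underfocus).
#' @param cs spherical aberration in millimetres.
#' @param voltage acceleration voltage in kV.
#' @param amplitude_contrast amplitude-contrast fraction A in \[0, 1\].
#' @param pixel_size detector pixel size in Angstrom.
#' @return object of class `ctf_params`.
#' @export
ctf_params <- function(defocus = 2.0, cs = 2.0, voltage = 300,
                       amplitude_contrast = 0.07, pixel_size = 5) {
  if (defocus <= 0 && !(cs == 0 && amplitude_contrast == 1))
    stop_confmap("defocus must be positive (underfocus magnitude in um)")
  if (amplitude_contrast < 0 || amplitude_contrast > 1)
    stop_confmap("amplitude_contrast must lie in [0, 1]")
  structure(list(defocus = defocus, cs = cs, voltage = voltage,
                 amplitude_contrast = amplitude_contrast,
                 pixel_size = pixel_size),
            class = "ctf_params")
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv acceleration voltage in kV.
#' @return wavelength in Angstrom (0.0197 A at 300 kV).
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Evaluate the CTF on the discrete frequency grid
#'
#' Returns the radially symmetric contrast transfer function evaluated on the
#' 2D discrete Fourier frequency grid of an image of the given shape (layout
#' matching [stats::fft()] output, zero frequency first).
#'
#' @param params a [ctf_params()].
#' @param grid_shape image side length in pixels (square grids only).
#' @return a `grid_shape x grid_shape` real matrix.
#' @export
ctf_function <- function(params, grid_shape) {
  stopifnot(inherits(params, "ctf_params"))
  n <- as.integer(grid_shape[1])
  k <- freq_radius(n, params$pixel_size)      # 1/A
  lambda <- electron_wavelength(params$voltage)
  dz <- params$defocus * 1e4                  # um -> A
  cs <- params$cs * 1e7                       # mm -> A
  gamma <- pi * lambda * dz * k^2 - (pi / 2) * cs * lambda^3 * k^4
  A <- params$amplitude_contrast
  -(sqrt(1 - A^2) * sin(gamma) + A * cos(gamma))
}

#' Apply a CTF to an image
#'
#' Multiplies the forward Fourier transform of the image by the CTF and
#' transforms back; equivalent to circular convolution with the microscope
#' point-spread function.
#'
#' @param image square numeric matrix.
#' @param params a [ctf_params()], or a precomputed real filter matrix of the
#'   same shape as `image`.
#' @return real matrix of the same shape.
#' @export
apply_ctf <- function(image, params) {
  if (!is_square_matrix(image)) stop_confmap("image must be a square matrix")
  flt <- if (inherits(params, "ctf_params")) ctf_function(params, nrow(image))
         else params
  if (!all(dim(flt) == dim(image)))
    stop_confmap("filter shape (%d x %d) does not match image (%d x %d)",
                 nrow(flt), ncol(flt), nrow(image), ncol(image))
  out <- ifft2(fft2(image) * flt)
  resid <- max(abs(Im(out))) / max(abs(Re(out)) + 1e-300)
  if (resid > 1e-6)
    warning(sprintf("imaginary residue %.2e after CTF application", resid))
  Re(out)
}
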