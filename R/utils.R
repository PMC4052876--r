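#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm rpois runif sd var median quantile cor
#' @importFrom utils read.csv write.csv modifyList
NULL

## Discrete FFT sample frequencies (cycles per unit), matching the layout of
## stats::fft output: 0, 1/(n*d), ..., then negative frequencies.
fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

## |k| on the 2D discrete frequency grid of an n x n image.
freq_radius <- function(n, pixel_size = 1) {
  f <- fft_freq(n, d = pixel_size)
  sqrt(outer(f^2, f^2, `+`))
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

## Derive a stream of child seeds from one master seed, staying < 2^31.
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) + 1000003 * seq_len(n)) %% .Machine$integer.max
}

stop_confmap <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)
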