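# Smooth Gaussian random-field helpers.
#
# Smoothing uses circular (FFT) convolution with a separable Gaussian kernel.
# Wrap-around keeps the field stationary across the grid, which makes kernel
# FWHM and field smoothness relate exactly; masks are applied afterwards, so
# edge effects never enter in-mask statistics.

fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# Periodic 1D Gaussian kernel of length n, normalized to sum 1.
gauss_kernel_1d <- function(n, fwhm) {
  sigma <- fwhm_to_sigma(fwhm)
  if (sigma <= 0) {
    k <- numeric(n)
    k[1] <- 1
    return(k)
  }
  d <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-d^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian-smooth a 3D array (circular convolution)
#'
#' @param x 3D numeric array.
#' @param fwhm Smoothing kernel FWHM in voxels; scalar (isotropic) or
#'   length 3.
#' @return Smoothed array of the same shape.
#' @export
smooth_field <- function(x, fwhm) {
  stopifnot(length(dim(x)) == 3L)
  fwhm <- rep_len(fwhm, 3L)
  if (all(fwhm <= 0)) return(x)
  d <- dim(x)
  k1 <- gauss_kernel_1d(d[1], fwhm[1])
  k2 <- gauss_kernel_1d(d[2], fwhm[2])
  k3 <- gauss_kernel_1d(d[3], fwhm[3])
  K <- outer(outer(fft(k1), fft(k2)), fft(k3))
  Re(fft(fft(x) * K, inverse = TRUE)) / prod(d)
}

# Smoothed white-noise field rescaled to unit SD (and zero mean) inside the
# mask, then multiplied by `sigma`. Decouples smoothness from variance.
# Consumes RNG state; callers seed via with_seed().
random_smooth_field <- function(grid_shape, fwhm, mask, sigma = 1) {
  w <- array(stats::rnorm(prod(grid_shape)), dim = grid_shape)
  f <- smooth_field(w, fwhm)
  v <- f[mask]
  f <- (f - mean(v)) / stats::sd(v)
  f[!mask] <- 0
  f * sigma
}
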