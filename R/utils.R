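# Internal numeric helpers shared across modules.
#
# Image convention (used everywhere in the package):
#   * images are numeric matrices; row index i is the scan axis y, column
#     index j is x; pixel (i, j) has its centre at
#     ((j - 1) * pixel_nm, (i - 1) * pixel_nm) in object space
#   * pattern lines run along rows (constant y), the scan steps in +y
#   * rotation angles are counterclockwise in the displayed orientation
#     (row 1 at the top), i.e. the mathematical sense applied to (x, -y)
# Frequency convention: cycles/nm, FFT layout with DC at [1, 1] unless a
# function is documented to return the shifted (DC-centred) layout.

#' @keywords internal
fft_freqs <- function(n, d = 1) {
  k <- seq_len(n) - 1L
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / (n * d)
}

#' @keywords internal
fft2 <- function(x) stats::fft(x)

#' @keywords internal
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @keywords internal
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))]
}

#' @keywords internal
ifftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((nr - floor(nr / 2) + 1):nr, 1:(nr - floor(nr / 2))),
    c((nc - floor(nc / 2) + 1):nc, 1:(nc - floor(nc / 2)))]
}

# Radial frequency magnitude |k| (cycles/nm) on the unshifted FFT lattice.
#' @keywords internal
freq_radius <- function(n, pixel_nm) {
  f <- fft_freqs(n, pixel_nm)
  kx <- matrix(f, nrow = n, ncol = n, byrow = TRUE)
  ky <- matrix(f, nrow = n, ncol = n)
  sqrt(kx^2 + ky^2)
}

# Circular convolution of a real image with a transfer function given on
# the unshifted frequency lattice (zero-phase kernels blur in place).
#' @keywords internal
conv_tf <- function(img, tf) {
  Re(ifft2(fft2(img) * tf))
}

# Gaussian low-pass transfer function with a given real-space FWHM (nm).
#' @keywords internal
gaussian_tf <- function(n, pixel_nm, fwhm_nm) {
  sigma <- fwhm_nm / (2 * sqrt(2 * log(2)))
  k2 <- freq_radius(n, pixel_nm)^2
  exp(-2 * pi^2 * sigma^2 * k2)
}

# Direct (zoomed) 2-D DFT of a complex image evaluated at arbitrary
# frequencies, in cycles/pixel.  kx/ky are equal-length vectors of
# evaluation points; coordinates are 0-based pixel indices.
#' @keywords internal
zoom_dft <- function(img, kx, ky) {
  n <- nrow(img); m <- ncol(img)
  y <- 0:(n - 1); x <- 0:(m - 1)
  ey <- exp(-2i * pi * outer(ky, y))        # |k| x n
  ex <- exp(-2i * pi * outer(x, kx))        # m x |k|
  rowSums((ey %*% img) * t(ex))
}

# 2-D Hann window.
#' @keywords internal
hann2 <- function(n, m = n) {
  # periodic form: the DFT kernel then has exact two-bin support, so
  # on-lattice tones leak nothing beyond their immediate neighbours
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  wx <- 0.5 - 0.5 * cos(2 * pi * (0:(m - 1)) / m)
  outer(wy, wx)
}

# Mean over the disk inscribed in a square matrix.
#' @keywords internal
inscribed_disk_mean <- function(img) {
  n <- nrow(img)
  c0 <- (n + 1) / 2
  d2 <- outer(((1:n) - c0)^2, ((1:n) - c0)^2, "+")
  mean(img[d2 <= ((n - 1) / 2)^2])
}

#' @keywords internal
is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

#' @keywords internal
stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
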