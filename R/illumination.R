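#' Sequential line-scan illumination pattern specification
#'
#' Describes the striped excitation pattern built up by stepping the
#' two-photon line focus across the field: pattern period, number of phase
#' steps, optical orientation angles and the line profile. The phase step
#' is exactly `spacing_nm / n_phases`.
#'
#' @param spacing_nm Pattern period p in nm.
#' @param line_profile A [line_profile_2p()] object.
#' @param n_phases Number of phase steps (>= 3; >= `2 * order + 1` for the
#'   band-separation order used downstream).
#' @param angles_deg Optical pattern orientations in degrees, distinct
#'   modulo 180.
#' @param polarization_contrast Scalar in `[0, 1]` multiplying the AC
#'   content of the pattern; models residual depolarization when the
#'   half-wave plate compensation is imperfect.
#' @return An object of class `line_pattern_spec`.
#' @export
line_pattern_spec <- function(spacing_nm, line_profile,
                              n_phases = 5L,
                              angles_deg = c(0, 60, 120),
                              polarization_contrast = 1) {
  stopifnot_scalar(spacing_nm, "spacing_nm", positive = TRUE)
  if (!inherits(line_profile, "line_profile"))
    stop("line_profile must be created with line_profile_2p()")
  n_phases <- as.integer(n_phases)
  if (n_phases < 3L) stop("n_phases must be >= 3")
  if (anyDuplicated(round(angles_deg %% 180, 9)))
    stop("pattern angles must be distinct modulo 180 degrees")
  if (polarization_contrast < 0 || polarization_contrast > 1)
    stop("polarization_contrast must lie in [0, 1]")
  structure(list(spacing_nm = spacing_nm,
                 n_phases = n_phases,
                 angles_deg = angles_deg,
                 line_profile = line_profile,
                 polarization_contrast = polarization_contrast),
            class = "line_pattern_spec")
}

#' @export
print.line_pattern_spec <- function(x, ...) {
  cat(sprintf("Line pattern: period %g nm, %d phases, angles [%s] deg\n",
              x$spacing_nm, x$n_phases,
              paste(x$angles_deg, collapse = ", ")))
  invisible(x)
}

# Line centre positions (nm) for one phase, covering [lo, hi] plus one full
# period and the profile support beyond both edges (boundary-ripple guard).
#' @keywords internal
line_positions <- function(spec, phase_index, lo_nm, hi_nm) {
  p <- spec$spacing_nm
  off <- phase_index * p / spec$n_phases
  pad <- p + spec$line_profile$support_nm
  j <- seq(floor((lo_nm - pad - off) / p), ceiling((hi_nm + pad - off) / p))
  j * p + off
}

#' Build one phase of the sequential line-scan pattern
#'
#' Sums the two-photon line profile over the line positions
#' `y_j = j p + phase_index * p / n_phases`. Lines are parallel to rows;
#' the scan direction is +y (down rows). The pattern is periodic with
#' period p along y within edge effects.
#'
#' @param spec A [line_pattern_spec()].
#' @param phase_index Integer in `0:(n_phases - 1)`.
#' @param frame_px Frame side length in pixels.
#' @param pixel_nm Pixel pitch in nm.
#' @return A `frame_px` x `frame_px` matrix of excitation intensity.
#' @export
build_pattern <- function(spec, phase_index, frame_px, pixel_nm) {
  if (phase_index < 0 || phase_index >= spec$n_phases)
    stop("phase_index must lie in 0:(n_phases - 1)")
  if (spec$spacing_nm < 2 * pixel_nm)
    stop("pattern spacing below two pixels cannot be sampled")
  prof <- pattern_profile(spec, phase_index, frame_px, pixel_nm)
  matrix(prof, nrow = frame_px, ncol = frame_px)
}

# 1-D pattern profile along y for one phase (length frame_px).
#' @keywords internal
pattern_profile <- function(spec, phase_index, frame_px, pixel_nm) {
  y <- (0:(frame_px - 1)) * pixel_nm
  centers <- line_positions(spec, phase_index, 0, max(y))
  prof <- numeric(frame_px)
  f <- spec$line_profile$fun
  for (c0 in centers) prof <- prof + f(y - c0)
  pc <- spec$polarization_contrast
  if (pc < 1) {
    m0 <- mean(prof)
    prof <- m0 + pc * (prof - m0)
  }
  prof
}

#' First-harmonic excitation modulation of the line pattern
#'
#' Relative amplitude of the pattern's first spatial harmonic,
#' `m1 = |P1| / P0`, where `Pn` are the Fourier-series coefficients of the
#' periodic pattern (equivalently of the line profile by Poisson
#' summation). For a Gaussian two-photon profile of FWHM w this is
#' `exp(-pi^2 w^2 k^2 / (4 log 2))` with `k = 1/p`: it decreases strictly
#' as the pattern period shrinks and tends to 1 for isolated lines
#' (`p -> Inf`). The peak-normalised image-domain modulation depth of the
#' built pattern is `2 * m1` (see [modulation_contrast()]).
#'
#' @param spec A [line_pattern_spec()].
#' @return Modulation `m1` in `[0, 1]`.
#' @export
excitation_modulation <- function(spec) {
  p <- spec$spacing_nm
  lp <- spec$line_profile
  if (lp$shape == "gaussian") {
    m1 <- exp(-pi^2 * lp$fwhm_nm^2 / (4 * log(2) * p^2))
  } else {
    # Fourier coefficient ratio of the line profile at k = 1/p
    s <- lp$support_nm
    y <- seq(-s, s, length.out = 16384)
    v <- lp$fun(y)
    m1 <- abs(sum(v * exp(-2i * pi * y / p))) / sum(v)
  }
  spec$polarization_contrast * m1
}

#' Dove-prism field rotation mapping
#'
#' A Dove prism rotates the optical field by twice its mechanical rotation
#' angle: a 30 degree mechanical rotation yields a 60 degree field
#' rotation. `optical_to_mechanical()` returns the principal mechanical
#' angle in `[0, 180)`.
#'
#' @param alpha_deg Mechanical rotation angle(s) in degrees.
#' @return Optical field rotation in `[0, 360)` degrees.
#' @export
mechanical_to_optical <- function(alpha_deg) (2 * alpha_deg) %% 360

#' @rdname mechanical_to_optical
#' @param optical_deg Optical field rotation angle(s) in degrees.
#' @export
optical_to_mechanical <- function(optical_deg) (optical_deg %% 360) / 2

#' Rotate a square image about its centre
#'
#' Resamples a square frame rotated counterclockwise (in the displayed
#' orientation, row 1 at the top) by `theta_deg` about the frame centre.
#' Out-of-field pixels are zero-filled; quantitative metrics downstream are
#' evaluated on the inscribed disk to avoid the fill region.
#'
#' @param img Square numeric matrix.
#' @param theta_deg Rotation angle in degrees (counterclockwise).
#' @param interpolation `"bilinear"` (default) or `"bicubic"`.
#' @return Rotated matrix of the same size.
#' @export
rotate_image <- function(img, theta_deg, interpolation = c("bilinear", "bicubic")) {
  interpolation <- match.arg(interpolation)
  if (!is_square_matrix(img)) stop("rotation requires a square frame")
  th <- theta_deg %% 360
  if (th == 0) return(img)
  n <- nrow(img)
  c0 <- (n + 1) / 2
  a <- th * pi / 180
  # displayed-CCW rotation: with y down the screen this is a clockwise
  # rotation of the (col, row) coordinate frame; source coords are the
  # inverse map of the output lattice
  co <- cos(a); si <- sin(a)
  xo <- matrix((1:n) - c0, nrow = n, ncol = n, byrow = TRUE)
  yo <- matrix((1:n) - c0, nrow = n, ncol = n)
  xs <- co * xo - si * yo + c0
  ys <- si * xo + co * yo + c0
  if (interpolation == "bilinear") interp_bilinear(img, xs, ys)
  else interp_bicubic(img, xs, ys)
}

#' Digital back rotation of a camera frame
#'
#' Rotates a raw frame by `+optical_angle_deg` about the frame centre so
#' that all pattern orientations share a common sample frame before SIM
#' reconstruction; inverse of the field rotation applied during
#' acquisition.
#'
#' @param frame Square numeric matrix.
#' @param optical_angle_deg Optical field rotation of the acquisition in
#'   degrees.
#' @param interpolation Passed to [rotate_image()].
#' @return The back-rotated frame.
#' @export
digital_back_rotation <- function(frame, optical_angle_deg,
                                  interpolation = "bilinear") {
  rotate_image(frame, optical_angle_deg, interpolation)
}

#' @keywords internal
interp_bilinear <- function(img, xs, ys) {
  n <- nrow(img); m <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- matrix(0, n, m)
  ok <- x0 >= 1 & x0 + 1 <= m & y0 >= 1 & y0 + 1 <= n
  ix <- x0[ok]; iy <- y0[ok]; gx <- fx[ok]; gy <- fy[ok]
  i00 <- (ix - 1) * n + iy
  out[ok] <- img[i00] * (1 - gx) * (1 - gy) +
    img[i00 + n] * gx * (1 - gy) +
    img[i00 + 1] * (1 - gx) * gy +
    img[i00 + n + 1] * gx * gy
  out
}

#' @keywords internal
interp_bicubic <- function(img, xs, ys) {
  # Catmull-Rom in both directions
  n <- nrow(img); m <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  out <- matrix(0, n, m)
  ok <- x0 >= 2 & x0 + 2 <= m & y0 >= 2 & y0 + 2 <= n
  ix <- x0[ok]; iy <- y0[ok]; gx <- fx[ok]; gy <- fy[ok]
  w <- function(t, k) {
    # Catmull-Rom weights for offsets -1, 0, 1, 2
    switch(k,
      `1` = ((-t + 2) * t - 1) * t / 2,
      `2` = (((3 * t - 5) * t) * t + 2) / 2,
      `3` = ((-3 * t + 4) * t + 1) * t / 2,
      `4` = ((t - 1) * t * t) / 2)
  }
  acc <- numeric(sum(ok))
  for (dy in -1:2) {
    rowacc <- numeric(sum(ok))
    for (dx in -1:2) {
      idx <- (ix + dx - 1) * n + (iy + dy)
      rowacc <- rowacc + img[idx] * w(gx, as.character(dx + 2))
    }
    acc <- acc + rowacc * w(gy, as.character(dy + 2))
  }
  out[ok] <- acc
  out
}
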