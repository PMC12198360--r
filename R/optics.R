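#' Optical configuration for the microscope model
#'
#' Bundles the optics and camera geometry used by the simulator and the
#' reconstruction: objective numerical aperture, two-photon excitation
#' wavelength, detected emission band, object-space pixel pitch and frame
#' size. Emission is blue-shifted relative to the (infrared) two-photon
#' excitation, so `lambda_em_max < lambda_ex` is enforced.
#'
#' @param na Numerical aperture of the objective (dimensionless, > 0).
#' @param lambda_ex_nm Two-photon excitation wavelength in nm.
#' @param lambda_em_min_nm,lambda_em_max_nm Detection band edges in nm.
#' @param pixel_nm Object-space pixel pitch in nm.
#' @param frame_px Frame side length in pixels (square frames).
#' @param immersion_index Refractive index of the immersion medium.
#'
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config()
#' cfg$pixel_nm
#' @export
optical_config <- function(na = 1.49,
                           lambda_ex_nm = 800,
                           lambda_em_min_nm = 525,
                           lambda_em_max_nm = 650,
                           pixel_nm = 65,
                           frame_px = 512,
                           immersion_index = 1.515) {
  stopifnot_scalar(na, "na", positive = TRUE)
  stopifnot_scalar(lambda_ex_nm, "lambda_ex_nm", positive = TRUE)
  stopifnot_scalar(lambda_em_min_nm, "lambda_em_min_nm", positive = TRUE)
  stopifnot_scalar(lambda_em_max_nm, "lambda_em_max_nm", positive = TRUE)
  stopifnot_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  stopifnot_scalar(frame_px, "frame_px", positive = TRUE)
  if (lambda_em_min_nm >= lambda_em_max_nm)
    stop("detection band requires lambda_em_min_nm < lambda_em_max_nm")
  if (lambda_em_max_nm >= lambda_ex_nm)
    stop("two-photon emission must be blue of excitation: lambda_em_max_nm < lambda_ex_nm")
  frame_px <- as.integer(frame_px)
  if (frame_px < 16L) stop("frame_px too small (need >= 16)")
  cfg <- structure(
    list(na = na,
         lambda_ex_nm = lambda_ex_nm,
         lambda_em_min_nm = lambda_em_min_nm,
         lambda_em_max_nm = lambda_em_max_nm,
         pixel_nm = pixel_nm,
         frame_px = frame_px,
         immersion_index = immersion_index),
    class = "optical_config")
  # detection band must at least be Nyquist-sampled; the extended SIM band
  # is checked again at reconstruction time where the pattern is known
  if (1 / (2 * pixel_nm) < detection_cutoff(cfg))
    warning("pixel_nm does not Nyquist-sample the detection cutoff 2*NA/lambda_em")
  cfg
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  NA %.2f, excitation %g nm, detection %g-%g nm\n",
              x$na, x$lambda_ex_nm, x$lambda_em_min_nm, x$lambda_em_max_nm))
  cat(sprintf("  %d x %d px at %g nm/px (FOV %.2f um)\n",
              x$frame_px, x$frame_px, x$pixel_nm,
              x$frame_px * x$pixel_nm / 1000))
  invisible(x)
}

#' Band-centre effective emission wavelength
#' @param cfg An [optical_config()].
#' @return Wavelength in nm.
#' @export
lambda_eff_default <- function(cfg) (cfg$lambda_em_min_nm + cfg$lambda_em_max_nm) / 2

#' Detection cutoff frequency
#'
#' Incoherent detection cutoff `k_c = 2 NA / lambda_eff` in cycles/nm.
#'
#' @param cfg An [optical_config()].
#' @param lambda_eff_nm Effective emission wavelength (default: band centre).
#' @return Cutoff frequency in cycles/nm.
#' @export
detection_cutoff <- function(cfg, lambda_eff_nm = lambda_eff_default(cfg)) {
  2 * cfg$na / lambda_eff_nm
}

#' Ideal incoherent detection OTF
#'
#' Diffraction-limited incoherent optical transfer function of a circular
#' pupil ("chat" function), evaluated on the frame's frequency lattice:
#' `H(k) = (2/pi) (acos(rho) - rho sqrt(1 - rho^2))` with `rho = k / k_c`
#' and `k_c = 2 NA / lambda_eff`. Real, radially symmetric, 1 at DC,
#' identically 0 beyond the cutoff, monotone non-increasing.
#'
#' @param cfg An [optical_config()].
#' @param lambda_eff_nm Effective emission wavelength in nm; must lie in the
#'   configured detection band.
#' @param frame_px Lattice size (default `cfg$frame_px`).
#' @param pixel_nm Lattice pitch (default `cfg$pixel_nm`).
#' @param shifted If `TRUE` return the DC-centred layout; default is the
#'   unshifted FFT layout (DC at `[1, 1]`).
#' @return A `frame_px` x `frame_px` numeric matrix.
#' @export
detection_otf <- function(cfg, lambda_eff_nm = lambda_eff_default(cfg),
                          frame_px = cfg$frame_px, pixel_nm = cfg$pixel_nm,
                          shifted = FALSE) {
  if (lambda_eff_nm < cfg$lambda_em_min_nm || lambda_eff_nm > cfg$lambda_em_max_nm)
    stop("lambda_eff_nm outside the configured detection band")
  kc <- detection_cutoff(cfg, lambda_eff_nm)
  if (1 / (2 * pixel_nm) < kc)
    stop("frequency lattice too coarse to represent the detection cutoff; ",
         "decrease pixel_nm")
  otf <- otf_radial(freq_radius(frame_px, pixel_nm), kc)
  if (shifted) fftshift2(otf) else otf
}

# Chat-function OTF as a function of |k| (vectorised).
#' @keywords internal
otf_radial <- function(k, kc) {
  rho <- pmin(k / kc, 1)
  (2 / pi) * (acos(rho) - rho * sqrt(pmax(0, 1 - rho^2)))
}

#' Detection PSF kernel
#'
#' Real-space point spread function matching [detection_otf()], returned in
#' unshifted (wrap-around, centred at `[1, 1]`) layout and normalised to
#' unit sum, ready for circular convolution.
#'
#' @inheritParams detection_otf
#' @return A numeric matrix summing to 1.
#' @export
detection_psf <- function(cfg, lambda_eff_nm = lambda_eff_default(cfg),
                          frame_px = cfg$frame_px, pixel_nm = cfg$pixel_nm) {
  otf <- detection_otf(cfg, lambda_eff_nm, frame_px, pixel_nm)
  psf <- pmax(Re(ifft2(otf)), 0)
  psf / sum(psf)
}

#' Effective two-photon excitation line profile
#'
#' Cross-sectional intensity profile of the scanned excitation line in the
#' direction perpendicular to the line. The two-photon signal is
#' proportional to the squared one-photon intensity, so the returned
#' profile is the square of the chosen one-photon line profile, normalised
#' to unit peak. The default one-photon model is a Gaussian of FWHM
#' `0.5 * lambda_ex / NA` (scalar focal-line approximation); a sinc^2
#' ("airy") line profile with its first zero at `lambda_ex / (2 NA)` is
#' available as an alternative.
#'
#' @param cfg An [optical_config()].
#' @param shape `"gaussian"` (default) or `"airy"`.
#' @param fwhm_1p_nm One-photon intensity FWHM in nm; default
#'   `0.5 * lambda_ex_nm / na`.
#' @return An object of class `line_profile` with elements `fun` (the
#'   vectorised 2P intensity profile over offsets in nm), `fwhm_nm` (2P
#'   FWHM), `fwhm_1p_nm`, `shape` and `support_nm` (practical half-support).
#' @examples
#' lp <- line_profile_2p(optical_config())
#' lp$fwhm_nm   # approximately 190 nm at NA 1.49, 800 nm excitation
#' @export
line_profile_2p <- function(cfg, shape = c("gaussian", "airy"),
                            fwhm_1p_nm = 0.5 * cfg$lambda_ex_nm / cfg$na) {
  shape <- match.arg(shape)
  stopifnot_scalar(fwhm_1p_nm, "fwhm_1p_nm", positive = TRUE)
  if (shape == "gaussian") {
    a <- 4 * log(2) / fwhm_1p_nm^2
    fun <- function(y_nm) exp(-2 * a * y_nm^2)      # (exp(-a y^2))^2
    fwhm2 <- fwhm_1p_nm / sqrt(2)
    support <- 3 * fwhm_1p_nm
  } else {
    # 1P intensity sinc^2 with first zero at z0 = lambda/(2 NA) scaled so
    # that its FWHM matches fwhm_1p_nm; squaring gives sinc^4
    z0 <- fwhm_1p_nm / 0.8859       # sinc^2 FWHM = 0.8859 * first zero
    fun <- function(y_nm) {
      s <- ifelse(y_nm == 0, 1, sin(pi * y_nm / z0) / (pi * y_nm / z0))
      s^4
    }
    fwhm2 <- uniroot(function(y) fun(y) - 0.5, c(1e-9, z0))$root * 2
    support <- 12 * z0              # slow sinc^4 tails
  }
  structure(list(fun = fun, fwhm_nm = fwhm2, fwhm_1p_nm = fwhm_1p_nm,
                 shape = shape, support_nm = support),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("Two-photon line profile (%s): 1P FWHM %.1f nm -> 2P FWHM %.1f nm\n",
              x$shape, x$fwhm_1p_nm, x$fwhm_nm))
  invisible(x)
}
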