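#' Camera acquisition configuration
#'
#' Parameters of the forward camera model: shutter mode, lightsheet
#' exposure-band geometry and timing, depth-dependent scattering and the
#' photon/read-noise model.
#'
#' Modes: `"RS"` (rolling shutter, full-frame accumulation), `"LSS"`
#' (lightsheet shutter: only a band of `band_rows` rows co-moving with the
#' excitation line is exposed, rejecting scattered light from neighbouring
#' lines) and `"POINT"` (line-integrating detector, the point-scanning
#' two-photon analogue for contrast comparisons).
#'
#' @param mode One of `"LSS"`, `"RS"`, `"POINT"`.
#' @param band_rows Odd number of exposed rows in LSS mode (default 7).
#' @param line_exposure_ms Exposure per line in ms.
#' @param scatter_fraction Fraction f in `[0, 1)` of emitted light routed
#'   to the wide scattering halo (used when no per-plane depth is given).
#' @param scatter_kernel_fwhm_nm FWHM of the isotropic Gaussian scattering
#'   halo in nm.
#' @param system_blur_fwhm_nm FWHM of an additional Gaussian blur of the
#'   detected emission modelling the difference between the as-built
#'   system PSF and the design PSF (residual aberrations, index
#'   mismatch); processing downstream assumes the design OTF. Default 0
#'   (ideal system).
#' @param scatter_length_um Depth constant l_s of the scattering model
#'   `f(z) = 1 - exp(-z / l_s)`.
#' @param excitation_length_um Optional two-photon excitation attenuation
#'   length; intensity scales as `exp(-2 z / l_ex)` (default `Inf`, off).
#' @param photon_scale Expected photo-electrons per unit density per unit
#'   excitation (> 0).
#' @param read_noise_e Gaussian camera read noise (electrons RMS).
#' @param noise Apply Poisson + read noise (`TRUE`) or return noise-free
#'   expected electrons (`FALSE`).
#' @param seed RNG seed used once per acquired stack.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(mode = c("LSS", "RS", "POINT"),
                               band_rows = 7L,
                               line_exposure_ms = 5,
                               scatter_fraction = 0,
                               scatter_kernel_fwhm_nm = 3000,
                               system_blur_fwhm_nm = 0,
                               scatter_length_um = 25,
                               excitation_length_um = Inf,
                               photon_scale = 500,
                               read_noise_e = 1.5,
                               noise = TRUE,
                               seed = 1L) {
  mode <- match.arg(mode)
  band_rows <- as.integer(band_rows)
  if (band_rows < 1L || band_rows %% 2L == 0L)
    stop("band_rows must be odd and >= 1")
  if (scatter_fraction < 0 || scatter_fraction >= 1)
    stop("scatter_fraction must lie in [0, 1)")
  stopifnot_scalar(photon_scale, "photon_scale", positive = TRUE)
  stopifnot_scalar(line_exposure_ms, "line_exposure_ms", positive = TRUE)
  structure(list(mode = mode, band_rows = band_rows,
                 line_exposure_ms = line_exposure_ms,
                 scatter_fraction = scatter_fraction,
                 scatter_kernel_fwhm_nm = scatter_kernel_fwhm_nm,
                 system_blur_fwhm_nm = system_blur_fwhm_nm,
                 scatter_length_um = scatter_length_um,
                 excitation_length_um = excitation_length_um,
                 photon_scale = photon_scale,
                 read_noise_e = read_noise_e,
                 noise = isTRUE(noise),
                 seed = seed),
            class = "acquisition_config")
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf("Acquisition: %s mode, band %d rows, %g ms/line, f_scatter %g%s\n",
              x$mode, x$band_rows, x$line_exposure_ms, x$scatter_fraction,
              if (x$noise) sprintf(", %g e-/unit + %g e- read noise",
                                   x$photon_scale, x$read_noise_e)
              else ", noise-free"))
  invisible(x)
}

#' Lightsheet-shutter timing model
#'
#' In lightsheet shutter mode the camera advances the exposure band by one
#' row every `line_exposure / band_rows`; a full readout therefore takes
#' `line_exposure + (frame_rows - 1) * line_time`. With the default 5 ms
#' line exposure and a 7-row band the line time is 714.286 microseconds
#' and a 1024-row frame takes 735.71 ms.
#'
#' @param acq An [acquisition_config()].
#' @param frame_rows Number of rows read out.
#' @return List with `line_time_ms` and `total_exposure_ms`.
#' @export
lss_timing <- function(acq, frame_rows) {
  line_time <- acq$line_exposure_ms / acq$band_rows
  list(line_time_ms = line_time,
       total_exposure_ms = acq$line_exposure_ms +
         (frame_rows - 1) * line_time)
}

#' Object-space extent of the exposure band
#'
#' @param acq An [acquisition_config()].
#' @param optics An [optical_config()].
#' @return List with `length_um` (band length across the field) and
#'   `width_nm` (band width, `band_rows * pixel_nm`).
#' @export
band_geometry <- function(acq, optics) {
  list(length_um = optics$frame_px * optics$pixel_nm / 1000,
       width_nm = acq$band_rows * optics$pixel_nm)
}

# Depth-dependent scatter fraction f(z) = 1 - exp(-z / l_s).
#' @keywords internal
scatter_fraction_at <- function(acq, depth_um) {
  if (is.null(depth_um)) return(acq$scatter_fraction)
  1 - exp(-depth_um / acq$scatter_length_um)
}

#' Simulate one camera frame
#'
#' Forward model for a single acquisition: the sample is rotated into the
#' camera frame by `-optical_angle_deg` (the field rotator aligns the
#' pattern with the camera rows), each scan line excites
#' `sample * lineprofile^2`, the emission is blurred by the detection PSF
#' and split into a ballistic part `(1 - f)` and a scattered part `f`
#' convolved with a wide Gaussian halo. RS accumulates every line over the
#' full frame; LSS accumulates only the rows inside the co-moving exposure
#' band; POINT integrates each line's emission along columns into the
#' line's row. Poisson noise is applied to the accumulated photo-electrons
#' followed by Gaussian read noise when `acq$noise` is `TRUE`.
#'
#' @param sample A [phantom][make_beads] (lattice must match `optics`).
#' @param optical_angle_deg Optical pattern orientation in degrees.
#' @param phase_index Phase step in `0:(n_phases - 1)`.
#' @param acq An [acquisition_config()].
#' @param optics An [optical_config()].
#' @param pattern A [line_pattern_spec()].
#' @param depth_um Imaging depth; when given it sets the scatter fraction
#'   via `f(z) = 1 - exp(-z / l_s)` and the optional excitation
#'   attenuation.
#' @return Numeric matrix of photo-electrons.
#' @export
acquire_frame <- function(sample, optical_angle_deg, phase_index, acq,
                          optics, pattern, depth_um = sample$depth_um) {
  n <- optics$frame_px
  if (!identical(dim(sample$density), c(n, n)))
    stop("sample lattice does not match the optics frame size")
  if (!isTRUE(all.equal(sample$pixel_nm, optics$pixel_nm)))
    stop("sample pixel pitch does not match the optics lattice")
  if (acq$band_rows > n && acq$mode == "LSS")
    warning("exposure band wider than the frame; lightsheet shutter ",
            "degenerates to full-frame (rolling shutter) integration")
  f <- scatter_fraction_at(acq, depth_um)
  exc_scale <- if (is.finite(acq$excitation_length_um) && !is.null(depth_um))
    exp(-2 * depth_um / acq$excitation_length_um) else 1
  s <- if (optical_angle_deg %% 360 == 0) sample$density
       else rotate_image(sample$density, -optical_angle_deg)
  otf <- detection_otf(optics, frame_px = n)
  if ((acq$system_blur_fwhm_nm %||% 0) > 0)
    otf <- otf * gaussian_tf(n, optics$pixel_nm, acq$system_blur_fwhm_nm)
  scat_tf <- if (f > 0) gaussian_tf(n, optics$pixel_nm,
                                    acq$scatter_kernel_fwhm_nm) else NULL
  detect <- function(emission_blurred) {
    if (f > 0)
      (1 - f) * emission_blurred + f * conv_tf(emission_blurred, scat_tf)
    else emission_blurred
  }
  full_band <- acq$band_rows >= n
  if (acq$mode == "RS" || (acq$mode == "LSS" && full_band)) {
    pat <- build_pattern(pattern, phase_index, n, optics$pixel_nm)
    acc <- detect(conv_tf(s * pat, otf))
  } else {
    y <- (0:(n - 1)) * optics$pixel_nm
    centers <- line_positions(pattern, phase_index, 0, max(y))
    prof <- pattern$line_profile$fun
    acc <- matrix(0, n, n)
    half_nm <- (acq$band_rows - 1) / 2 * optics$pixel_nm
    # depolarized fraction of each line excites a uniform background so
    # the summed excitation matches the polarization-scaled pattern
    pc <- pattern$polarization_contrast
    flat <- if (pc < 1)
      (1 - pc) * mean(pattern_profile(pattern, phase_index, n,
                                      optics$pixel_nm)) / length(centers)
    else 0
    for (c0 in centers) {
      g <- pc * prof(y - c0) + flat
      if (max(g) < 1e-12) next
      em <- detect(conv_tf(s * g, otf))
      if (acq$mode == "LSS") {
        rows <- which(abs(y - c0) <= half_nm + 1e-9)
        if (length(rows)) acc[rows, ] <- acc[rows, ] + em[rows, ]
      } else {                      # POINT: line-integrating detector
        r0 <- min(max(round(c0 / optics$pixel_nm) + 1, 1L), n)
        acc[r0, ] <- acc[r0, ] + colSums(em)
      }
    }
  }
  electrons <- exc_scale * acq$photon_scale * pmax(acc, 0)
  if (acq$noise) {
    electrons <- rpois(length(electrons), electrons) +
      rnorm(length(electrons), 0, acq$read_noise_e)
    electrons <- matrix(electrons, n, n)
  }
  electrons
}

#' Acquire a full SIM stack
#'
#' Acquires the canonical `n_angles x n_phases` frame sequence
#' (angle-major, phase-minor; 15 frames for 3 angles and 5 phases) with
#' one seeded RNG stream for the whole stack.
#'
#' @inheritParams acquire_frame
#' @return An object of class `sim_stack`: list of frames plus a per-frame
#'   metadata data frame (`angle_deg`, `phase_index`, `mode`, `depth_um`,
#'   `spacing_nm`) and the generating configurations.
#' @export
acquire_sim_stack <- function(sample, pattern, acq, optics,
                              depth_um = sample$depth_um) {
  if (!is.null(acq$seed)) set.seed(acq$seed)
  frames <- list()
  meta <- list()
  k <- 0L
  for (ang in pattern$angles_deg) {
    for (ph in 0:(pattern$n_phases - 1L)) {
      k <- k + 1L
      frames[[k]] <- acquire_frame(sample, ang, ph, acq, optics, pattern,
                                   depth_um = depth_um)
      meta[[k]] <- data.frame(frame = k, angle_deg = ang, phase_index = ph,
                              mode = acq$mode,
                              depth_um = depth_um %||% NA_real_,
                              spacing_nm = pattern$spacing_nm)
    }
  }
  structure(list(frames = frames, meta = do.call(rbind, meta),
                 pattern = pattern, optics = optics, acq = acq),
            class = "sim_stack")
}

#' @export
print.sim_stack <- function(x, ...) {
  cat(sprintf("SIM stack: %d frames (%d angles x %d phases), %s mode, %d px\n",
              length(x$frames), length(x$pattern$angles_deg),
              x$pattern$n_phases, x$acq$mode, nrow(x$frames[[1]])))
  invisible(x)
}

#' Acquire a depth series of single-phase frames
#'
#' Acquires one frame per tissue plane (same pattern angle and phase
#' throughout) with the scatter fraction increasing with depth as
#' `f(z) = 1 - exp(-z / l_s)`.
#'
#' @param planes List of `phantom` planes carrying `depth_um` (as produced
#'   by [make_tissue_stack()]).
#' @param pattern A [line_pattern_spec()].
#' @param acq An [acquisition_config()].
#' @param optics An [optical_config()].
#' @param angle_deg,phase_index Pattern orientation and phase used for all
#'   planes.
#' @return List with `frames` (one per plane), `depth_um` and `f` (the
#'   applied scatter fractions).
#' @export
acquire_depth_stack <- function(planes, pattern, acq, optics,
                                angle_deg = pattern$angles_deg[1],
                                phase_index = 0L) {
  if (any(vapply(planes, function(p) is.null(p$depth_um), logical(1))))
    stop("all planes must carry depth metadata")
  if (!is.null(acq$seed)) set.seed(acq$seed)
  frames <- lapply(planes, function(p)
    acquire_frame(p, angle_deg, phase_index, acq, optics, pattern,
                  depth_um = p$depth_um))
  depths <- vapply(planes, function(p) p$depth_um, numeric(1))
  list(frames = frames, depth_um = depths,
       f = vapply(depths, function(z) scatter_fraction_at(acq, z),
                  numeric(1)))
}
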