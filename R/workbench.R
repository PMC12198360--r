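# Experiment drivers and file I/O tying simulator, reconstruction and
# metrics together.

#' Resolution-improvement bound sweep
#'
#' Measures the maximum lateral resolution-improvement factor of SIM over
#' the pattern-averaged two-photon image by sweeping the pattern spatial
#' frequency upward (spacing downward) in a noise-free simulation of a
#' point target. Two pattern generation modes are compared:
#' `"sequential"` uses the stepwise line-scan pattern, whose excitation
#' modulation [excitation_modulation()] decays with pattern frequency; the
#' sweep stops when it no longer exceeds the reconstructability floor.
#' `"interference"` uses an ideal fully modulated sinusoid whose frequency
#' may reach the detection cutoff (the final sweep step is placed exactly
#' at the cutoff), the coherent-SIM reference case.
#'
#' Patterns are synthesised directly at each orientation in the common
#' sample frame and the reconstruction is fed the known pattern
#' parameters: the sweep quantifies the theoretical bound of the optical
#' configuration, not estimator robustness, and therefore bypasses the
#' detected-modulation gate (at the excitation floor the detected
#' modulation is far below it).
#'
#' @param optics An [optical_config()] (`frame_px` sets the sweep's frame
#'   size).
#' @param cfg A [recon_config()]; the default uses a near-zero Wiener
#'   regularisation matched to the sweep's noise-free data, so the weak
#'   outer band edges are not suppressed.
#' @param mode `"sequential"` or `"interference"`.
#' @param spacing_start_nm,spacing_step_nm Sweep start and step (nm).
#' @param threshold Excitation-modulation floor for the sequential sweep.
#' @param angles_deg Pattern orientations.
#' @param n_phases Phase steps per orientation.
#' @return An object of class `improvement_bound`: sweep table
#'   (`spacing_nm`, `m1`, `k_pattern`, `improvement_measured`,
#'   `improvement_support`), `max_improvement_factor` (measured by
#'   decorrelation analysis), `max_improvement_support` (support ratio
#'   `(k_c + k_p)/k_c` at the sweep maximum) and
#'   `reference_resolution_nm`.
#' @export
exp_improvement_bound <- function(optics,
                                  cfg = recon_config(wiener_w = 1e-6),
                                  mode = c("sequential", "interference"),
                                  spacing_start_nm = 400,
                                  spacing_step_nm = 10,
                                  threshold = cfg$modulation_threshold,
                                  angles_deg = c(0, 60, 120),
                                  n_phases = 5L) {
  mode <- match.arg(mode)
  n <- optics$frame_px
  px <- optics$pixel_nm
  kc <- detection_cutoff(optics)
  lp <- line_profile_2p(optics)
  spacings <- seq(spacing_start_nm, 2 * px, by = -spacing_step_nm)
  if (mode == "sequential") {
    m1 <- vapply(spacings, function(p)
      excitation_modulation(line_pattern_spec(p, lp, n_phases, angles_deg)),
      numeric(1))
    keep <- m1 > threshold
  } else {
    m1 <- rep(0.5, length(spacings))       # (1 + cos): |c1|/c0 = 1/2
    keep <- 1 / spacings <= kc
    spacings <- c(spacings[keep], 1 / kc)  # final step exactly at cutoff
    m1 <- c(m1[keep], 0.5)
    keep <- rep(TRUE, length(spacings))
  }
  if (!any(keep)) stop("no reconstructable step in the sweep")
  spacings <- spacings[keep]
  m1 <- m1[keep]
  otf <- detection_otf(optics, frame_px = n)
  # point target at the lattice centre
  s <- matrix(0, n, n)
  s[n / 2 + 1, n / 2 + 1] <- 1
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE) * px
  yg <- matrix(0:(n - 1), n, n) * px
  phases_true <- -2 * pi * (0:(n_phases - 1)) / n_phases
  # the reference is measured on the same upsampled lattice as the SIM
  # output so the estimator's fixed edge smear cancels in the ratio
  ref_img <- conv_tf(s, otf)
  ref_up <- Re(ifft2(upsample_spectrum(fft2(ref_img), cfg$upsample)))
  ref_res <- decorrelation_resolution(ref_up, px / cfg$upsample,
                                      window = FALSE)$resolution_nm
  one_period <- function(p, spec) {
    # base pattern value over one period (phase 0), fine lookup table
    u <- seq(0, p, length.out = 4097)
    if (mode == "interference") 1 + cos(2 * pi * u / p)
    else {
      centers <- line_positions(spec, 0, 0, p)
      v <- numeric(length(u))
      for (c0 in centers) v <- v + spec$line_profile$fun(u - c0)
      v
    }
  }
  rows <- vector("list", length(spacings))
  for (i in seq_along(spacings)) {
    p <- spacings[i]
    spec <- line_pattern_spec(max(p, 2 * px + 1e-9), lp, n_phases, angles_deg)
    base <- one_period(p, spec)
    ugrid <- seq(0, p, length.out = 4097)
    band_groups <- list(); k_vectors <- list()
    for (a in seq_along(angles_deg)) {
      th <- angles_deg[a] * pi / 180
      k <- c(cos(th), sin(th)) / p
      u <- (xg * cos(th) + yg * sin(th))
      frames <- lapply(0:(n_phases - 1), function(j) {
        shift <- j * p / n_phases
        pat <- matrix(stats::approx(ugrid, base, xout = (u - shift) %% p,
                                    rule = 2)$y, n, n)
        conv_tf(s * pat, otf)
      })
      band_groups[[a]] <- separate_bands(frames, phases_true,
                                         cfg$separation_order)
      k_vectors[[a]] <- k
    }
    sim <- wiener_reconstruct(band_groups, k_vectors,
                              rep(2 * m1[i], length(angles_deg)),
                              optics, cfg)
    sim_res <- decorrelation_resolution(sim, attr(sim, "pixel_nm"),
                                        window = FALSE)$resolution_nm
    rows[[i]] <- data.frame(spacing_nm = p, m1 = m1[i], k_pattern = 1 / p,
                            improvement_measured = ref_res / sim_res,
                            improvement_support = (kc + 1 / p) / kc)
  }
  tab <- do.call(rbind, rows)
  structure(list(mode = mode, table = tab,
                 max_improvement_factor = max(tab$improvement_measured),
                 max_improvement_support = max(tab$improvement_support),
                 reference_resolution_nm = ref_res,
                 estimator = "decorrelation"),
            class = "improvement_bound")
}

#' @export
print.improvement_bound <- function(x, ...) {
  cat(sprintf("Improvement bound (%s patterns, %d sweep steps)\n",
              x$mode, nrow(x$table)))
  cat(sprintf("  max improvement: %.3f (measured), %.3f (support ratio)\n",
              x$max_improvement_factor, x$max_improvement_support))
  invisible(x)
}

#' Modulation contrast versus imaging depth, RS versus LSS
#'
#' Acquires one patterned frame per tissue plane in rolling-shutter and
#' lightsheet-shutter mode with paired noise seeds, extracts the detected
#' modulation contrast at the pattern frequency for each, and reports both
#' curves together with the first depth at which each falls to the
#' reconstructability floor.
#'
#' @param optics An [optical_config()].
#' @param pattern A [line_pattern_spec()].
#' @param acq An [acquisition_config()] (mode is overridden per curve).
#' @param n_planes Number of depth planes.
#' @param z_step_um Axial step in micrometres.
#' @param seed Seed for phantom generation and acquisition noise.
#' @param reps Number of paired noise repetitions averaged per depth.
#' @param threshold Reconstructability floor.
#' @return An object of class `depth_series` with the per-depth table and
#'   crossing depths.
#' @export
exp_depth_series <- function(optics, pattern, acq, n_planes = 12L,
                             z_step_um = 0.5, seed = 1L, reps = 1L,
                             threshold = 0.1) {
  planes <- make_tissue_stack(n_planes, optics$frame_px, optics$pixel_nm,
                              z_step_um = z_step_um, seed = seed)
  k <- pattern_k_vector(pattern, angle_deg = pattern$angles_deg[1])
  c_rs <- matrix(0, n_planes, reps)
  c_lss <- matrix(0, n_planes, reps)
  for (r in seq_len(reps)) {
    for (m in c("RS", "LSS")) {
      a <- acq
      a$mode <- m
      a$seed <- seed + r                 # paired seeds across modes
      res <- acquire_depth_stack(planes, pattern, a, optics)
      cv <- vapply(res$frames, function(fr)
        modulation_contrast(fr, k, optics$pixel_nm), numeric(1))
      if (m == "RS") c_rs[, r] <- cv else c_lss[, r] <- cv
    }
  }
  tab <- data.frame(depth_um = vapply(planes, function(p) p$depth_um,
                                      numeric(1)),
                    f_scatter = 1 - exp(-vapply(planes, function(p)
                      p$depth_um, numeric(1)) / acq$scatter_length_um),
                    contrast_rs = rowMeans(c_rs),
                    contrast_lss = rowMeans(c_lss))
  first_below <- function(v) {
    i <- which(v <= threshold)
    if (length(i) == 0) NA_real_ else tab$depth_um[i[1]]
  }
  structure(list(table = tab,
                 crossing_rs_um = first_below(tab$contrast_rs),
                 crossing_lss_um = first_below(tab$contrast_lss),
                 threshold = threshold),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat("Depth series (modulation contrast vs depth)\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("  first depth at/below %.2f: RS %s um, LSS %s um\n",
              x$threshold,
              format(x$crossing_rs_um), format(x$crossing_lss_um)))
  invisible(x)
}

# Pattern frequency vector (cycles/nm) of a spec at a given optical
# orientation: at angle 0 the lines run along rows and the frequency
# points along +y, so the k direction is at 90 - angle from +x.
#' @keywords internal
pattern_k_vector <- function(pattern, angle_deg = 0) {
  th <- (90 - angle_deg) * pi / 180
  c(cos(th), sin(th)) / pattern$spacing_nm
}

#' Bead-field processing chain comparison
#'
#' Simulates a bead field (190 nm beads by default), acquires a full SIM
#' stack, and compares the bead FWHM across the four processing variants:
#' the pattern-averaged two-photon image, Richardson-Lucy deconvolution of
#' that image without SIM computation, SIM reconstruction without
#' deconvolution, and SIM reconstruction followed by deconvolution.
#'
#' @param optics An [optical_config()].
#' @param pattern A [line_pattern_spec()].
#' @param acq An [acquisition_config()].
#' @param cfg A [recon_config()].
#' @param n_beads Number of beads.
#' @param diameter_nm Bead diameter.
#' @param background Uniform background fluorophore density added to the
#'   bead field (out-of-focus and substrate fluorescence present in real
#'   bead slides).
#' @param seed Phantom seed.
#' @return An object of class `bead_chain` with `fwhm_nm` (named vector:
#'   `twopm`, `rl`, `sim`, `sim_rl`), the per-variant statistics and the
#'   reconstruction.
#' @export
exp_bead_chain <- function(optics, pattern, acq, cfg = recon_config(),
                           n_beads = 25L, diameter_nm = 190,
                           background = 0.1, seed = 2L) {
  sample <- make_beads(n_beads, optics$frame_px, optics$pixel_nm,
                       diameter_nm = diameter_nm, seed = seed)
  if (n_beads == 0L || nrow(sample$ground_truth$centers_nm) == 0L)
    stop("empty bead field: nothing to measure")
  sample$density <- sample$density + background
  stack <- acquire_sim_stack(sample, pattern, acq, optics)
  rec <- reconstruct(stack, cfg)
  ref <- rec$lil2pm %||% rec$wil2pm
  if (is.null(rec$lilsim))
    stop("SIM reconstruction refused; cannot compare the chain")
  psf <- detection_psf(optics, frame_px = nrow(ref))
  # deconvolution without SIM computation operates on the individual raw
  # frames, which are then superimposed
  st <- normalize_stack(back_rotate_stack(stack))
  rl <- lil2pm_average(lapply(st$frames, function(f)
    rl_deconvolve(pmax(f, 0), psf, cfg$rl_iterations)))
  simpsf <- sim_effective_psf(attr(rec$lilsim, "cutoff_cyc_nm"),
                              nrow(rec$lilsim), attr(rec$lilsim, "pixel_nm"))
  simrl <- rl_deconvolve(pmax(rec$lilsim, 0), simpsf, cfg$rl_iterations)
  ctr <- sample$ground_truth$centers_nm
  # half-maximum widths: the deconvolved modalities restore flat-top
  # disk profiles whose physical diameter a Gaussian fit underestimates
  stats <- list(
    twopm = fwhm_beads(ref, ctr, optics$pixel_nm, method = "halfmax"),
    rl = fwhm_beads(rl, ctr, optics$pixel_nm, method = "halfmax"),
    sim = fwhm_beads(rec$lilsim, ctr, attr(rec$lilsim, "pixel_nm"),
                     window_px = 24L, method = "halfmax"),
    sim_rl = fwhm_beads(simrl, ctr, attr(rec$lilsim, "pixel_nm"),
                        window_px = 24L, method = "halfmax"))
  structure(list(fwhm_nm = vapply(stats, `[[`, numeric(1), "mean_nm"),
                 stats = stats, reconstruction = rec,
                 diameter_nm = diameter_nm),
            class = "bead_chain")
}

#' @export
print.bead_chain <- function(x, ...) {
  cat("Bead processing chain (mean FWHM, nm)\n")
  print(round(x$fwhm_nm, 1))
  invisible(x)
}

#' Write / read a SIM stack as multi-page TIFF plus JSON sidecar
#'
#' Frames are stored as 32-bit TIFF pages scaled into `[0, 1]` by a
#' per-stack scale and integer offset recorded in a JSON sidecar next to
#' the TIFF (`<path>.json`), together with the per-frame metadata and the
#' generating configurations. Integer-valued stacks (e.g. rounded
#' photo-electron counts) are flagged in the sidecar and round-trip
#' exactly; continuous data round-trip with 32-bit quantisation
#' (relative error below 2^-32 of the dynamic range).
#'
#' @param stack A `sim_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_sim_stack <- function(stack, path) {
  frames <- stack$frames
  lo <- floor(min(vapply(frames, min, numeric(1)), 0))
  hi <- max(vapply(frames, max, numeric(1))) - lo
  scale <- max(hi, 1)
  integer_valued <- all(vapply(frames, function(f)
    isTRUE(all.equal(f, round(f), tolerance = 0)), logical(1)))
  pages <- lapply(frames, function(f) (f - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale = scale, offset = lo,
               integer_valued = integer_valued,
               meta = stack$meta,
               optics = unclass(stack$optics),
               pattern = pattern_to_list(stack$pattern),
               acq = unclass(stack$acq))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @keywords internal
sidecar_path <- function(path) paste0(path, ".json")

#' @keywords internal
pattern_to_list <- function(pattern) {
  list(spacing_nm = pattern$spacing_nm,
       n_phases = pattern$n_phases,
       angles_deg = pattern$angles_deg,
       polarization_contrast = pattern$polarization_contrast,
       profile_shape = pattern$line_profile$shape,
       fwhm_1p_nm = pattern$line_profile$fwhm_1p_nm)
}

#' @rdname write_sim_stack
#' @export
read_sim_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(pages, function(p) {
    f <- p * meta$scale + meta$offset
    if (isTRUE(meta$integer_valued)) round(f) else f
  })
  optics <- do.call(optical_config,
                    meta$optics[names(meta$optics) %in%
                                  names(formals(optical_config))])
  lp <- line_profile_2p(optics, shape = meta$pattern$profile_shape,
                        fwhm_1p_nm = meta$pattern$fwhm_1p_nm)
  pattern <- line_pattern_spec(meta$pattern$spacing_nm, lp,
                               meta$pattern$n_phases,
                               meta$pattern$angles_deg,
                               meta$pattern$polarization_contrast)
  acq <- do.call(acquisition_config,
                 meta$acq[names(meta$acq) %in%
                            names(formals(acquisition_config))])
  structure(list(frames = frames, meta = as.data.frame(meta$meta),
                 pattern = pattern, optics = optics, acq = acq),
            class = "sim_stack")
}

#' Write a phantom as TIFF plus ground-truth JSON sidecar
#'
#' @param phantom A `phantom`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  hi <- max(phantom$density, 1)
  scale <- 2^ceiling(log2(hi))
  tiff::writeTIFF(phantom$density / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale, pixel_nm = phantom$pixel_nm,
                            depth_um = phantom$depth_um,
                            ground_truth = phantom$ground_truth),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a structured experiment configuration (YAML or JSON)
#'
#' Recognised top-level sections: `name`, `seed`, `optics`, `pattern`,
#' `acquisition`, `reconstruction`, `output`. Unknown sections or unknown
#' fields inside a section produce a warning and are ignored rather than
#' an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list of the recognised sections.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("name", "seed", "optics", "pattern", "acquisition",
             "reconstruction", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config sections: ",
            paste(unknown, collapse = ", "))
  cfg[intersect(names(cfg), known)]
}

#' Build configuration objects from a parsed config list
#'
#' @param cfg List from [read_config()].
#' @return List with `optics`, `pattern`, `acq`, `recon` objects.
#' @export
build_configs <- function(cfg) {
  take <- function(x, fun) {
    x <- as.list(x)
    unknown <- setdiff(names(x), names(formals(fun)))
    if (length(unknown))
      warning("ignoring unknown config fields: ",
              paste(unknown, collapse = ", "))
    x[names(x) %in% names(formals(fun))]
  }
  optics <- do.call(optical_config, take(cfg$optics %||% list(),
                                         optical_config))
  pat <- as.list(cfg$pattern %||% list())
  known_pat <- c("spacing_nm", "n_phases", "angles_deg",
                 "polarization_contrast", "profile_shape", "fwhm_1p_nm")
  if (length(setdiff(names(pat), known_pat)))
    warning("ignoring unknown config fields: ",
            paste(setdiff(names(pat), known_pat), collapse = ", "))
  lp <- line_profile_2p(optics,
                        shape = pat$profile_shape %||% "gaussian",
                        fwhm_1p_nm = pat$fwhm_1p_nm %||%
                          (0.5 * optics$lambda_ex_nm / optics$na))
  pattern <- line_pattern_spec(pat$spacing_nm %||% 350, lp,
                               pat$n_phases %||% 5L,
                               pat$angles_deg %||% c(0, 60, 120),
                               pat$polarization_contrast %||% 1)
  acq <- do.call(acquisition_config, take(cfg$acquisition %||% list(),
                                          acquisition_config))
  recon <- do.call(recon_config, take(cfg$reconstruction %||% list(),
                                      recon_config))
  list(optics = optics, pattern = pattern, acq = acq, recon = recon)
}
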