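# Synthetic ground-truth samples. All phantoms are deterministic functions
# of their parameters and seed, so every downstream stage is testable
# without external data.

#' @keywords internal
new_phantom <- function(density, pixel_nm, ground_truth = list(),
                        depth_um = NULL) {
  stopifnot(is.matrix(density), all(density >= 0))
  structure(list(density = density, pixel_nm = pixel_nm,
                 ground_truth = ground_truth, depth_um = depth_um),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom: %d x %d px at %g nm/px (%s)\n",
              nrow(x$density), ncol(x$density), x$pixel_nm,
              x$ground_truth$kind %||% "generic"))
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fluorescent bead field phantom
#'
#' Randomly placed circular beads (default 190 nm diameter) rasterized
#' with 4x supersampling and box down-sampling, so sub-pixel centre
#' positions are meaningful for FWHM analysis. Placement is rejection
#' sampled with a minimum centre separation; if not all beads can be
#' placed within a bounded number of retries an error reports the achieved
#' count.
#'
#' @param n_beads Number of beads.
#' @param frame_px Frame side length in pixels.
#' @param pixel_nm Pixel pitch in nm.
#' @param diameter_nm Bead diameter in nm.
#' @param min_sep_nm Minimum centre-to-centre separation (>= diameter).
#' @param margin_nm Keep-out margin from the field edges.
#' @param intensity Bead fluorophore density.
#' @param seed RNG seed (required for reproducibility).
#' @return A `phantom` whose `ground_truth` records `centers_nm` (x, y) and
#'   `diameter_nm`.
#' @export
make_beads <- function(n_beads, frame_px, pixel_nm = 65,
                       diameter_nm = 190, min_sep_nm = 3 * diameter_nm,
                       margin_nm = 20 * pixel_nm, intensity = 1, seed = 1) {
  if (min_sep_nm < diameter_nm) stop("min_sep_nm must be >= diameter_nm")
  set.seed(seed)
  ext <- (frame_px - 1) * pixel_nm
  centers <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(centers) < n_beads && tries < 200L * max(1L, n_beads)) {
    tries <- tries + 1L
    cand <- runif(2, margin_nm, ext - margin_nm)
    if (nrow(centers) == 0 ||
        min(sqrt(colSums((t(centers) - cand)^2))) >= min_sep_nm)
      centers <- rbind(centers, cand)
  }
  if (nrow(centers) < n_beads)
    stop(sprintf("could only place %d of %d beads at min_sep_nm = %g",
                 nrow(centers), n_beads, min_sep_nm))
  dens <- matrix(0, frame_px, frame_px)
  if (n_beads > 0) {
    r <- diameter_nm / 2
    ss <- 4L
    for (b in seq_len(nrow(centers))) {
      cx <- centers[b, 1]; cy <- centers[b, 2]
      jlo <- max(1L, floor((cx - r) / pixel_nm) + 1L - 1L)
      jhi <- min(frame_px, ceiling((cx + r) / pixel_nm) + 1L + 1L)
      ilo <- max(1L, floor((cy - r) / pixel_nm) + 1L - 1L)
      ihi <- min(frame_px, ceiling((cy + r) / pixel_nm) + 1L + 1L)
      # supersampled subpixel centres within the patch
      sub <- (seq_len(ss) - 0.5) / ss - 0.5
      xs <- rep((jlo:jhi) - 1, each = ss) * pixel_nm +
        rep(sub * pixel_nm, times = jhi - jlo + 1)
      ys <- rep((ilo:ihi) - 1, each = ss) * pixel_nm +
        rep(sub * pixel_nm, times = ihi - ilo + 1)
      inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
      # box down-sample ss x ss blocks
      nyp <- ihi - ilo + 1; nxp <- jhi - jlo + 1
      cov <- matrix(0, nyp, nxp)
      for (dy in seq_len(ss)) for (dx in seq_len(ss))
        cov <- cov + inside[seq(dy, by = ss, length.out = nyp),
                            seq(dx, by = ss, length.out = nxp)]
      dens[ilo:ihi, jlo:jhi] <- dens[ilo:ihi, jlo:jhi] +
        intensity * cov / ss^2
    }
  }
  new_phantom(dens, pixel_nm,
              list(kind = "beads", centers_nm = centers,
                   diameter_nm = diameter_nm))
}

#' Line-pair calibration target phantom
#'
#' Pairs of parallel vertical lines with centre-to-centre gaps decreasing
#' from `start_gap_nm` in steps of `step_nm` down to `min_gap_nm`
#' (390, 360, ..., 150 nm by default), emulating a structured calibration
#' slide. Line width defaults to one object pixel: the imaged width is set
#' by the PSF.
#'
#' @param frame_px Frame side length in pixels.
#' @param pixel_nm Pixel pitch in nm.
#' @param start_gap_nm,step_nm,min_gap_nm Gap ladder definition in nm.
#' @param line_width_nm Physical line width in nm.
#' @param pair_spacing_nm Distance between consecutive pair centres.
#' @param intensity Fluorophore density on the lines.
#' @return A `phantom` whose `ground_truth` records `gaps_nm`,
#'   `pair_centers_x_nm` and `line_x_nm` (two columns).
#' @export
make_line_pairs <- function(frame_px, pixel_nm = 65,
                            start_gap_nm = 390, step_nm = 30,
                            min_gap_nm = 150, line_width_nm = pixel_nm,
                            pair_spacing_nm = 1600, intensity = 1) {
  if (min_gap_nm < 2 * pixel_nm)
    stop("min_gap_nm must be at least two pixels")
  gaps <- if (start_gap_nm < min_gap_nm) numeric(0)
          else seq(start_gap_nm, min_gap_nm, by = -step_nm)
  dens <- matrix(0, frame_px, frame_px)
  if (length(gaps) == 0)
    return(new_phantom(dens, pixel_nm, list(kind = "line_pairs",
                                            gaps_nm = numeric(0))))
  ext <- (frame_px - 1) * pixel_nm
  margin <- pair_spacing_nm / 2
  need <- (length(gaps) - 1) * pair_spacing_nm + 2 * margin
  if (need > ext)
    stop(sprintf("field (%.0f nm) too small for %d line pairs spaced %g nm",
                 ext, length(gaps), pair_spacing_nm))
  x0 <- (ext - (length(gaps) - 1) * pair_spacing_nm) / 2
  pair_centers <- x0 + (seq_along(gaps) - 1) * pair_spacing_nm
  line_x <- cbind(pair_centers - gaps / 2, pair_centers + gaps / 2)
  xpix <- (0:(frame_px - 1)) * pixel_nm
  col_profile <- numeric(frame_px)
  for (x in as.vector(line_x)) {
    # analytic 1-D fractional coverage of [x - w/2, x + w/2] per pixel
    lo <- pmax(xpix - pixel_nm / 2, x - line_width_nm / 2)
    hi <- pmin(xpix + pixel_nm / 2, x + line_width_nm / 2)
    col_profile <- col_profile + pmax(0, hi - lo) / pixel_nm
  }
  dens <- matrix(rep(intensity * col_profile, each = frame_px), frame_px)
  new_phantom(dens, pixel_nm,
              list(kind = "line_pairs", gaps_nm = gaps,
                   pair_centers_x_nm = pair_centers, line_x_nm = line_x))
}

#' Uniform fluorescent slide phantom
#'
#' @param frame_px Frame side length in pixels.
#' @param level Constant fluorophore density.
#' @param pixel_nm Pixel pitch in nm.
#' @return A `phantom`.
#' @export
make_uniform_slide <- function(frame_px, level = 1, pixel_nm = 65) {
  if (level < 0) stop("level must be >= 0")
  new_phantom(matrix(level, frame_px, frame_px), pixel_nm,
              list(kind = "uniform", level = level))
}

#' Scattering-tissue depth stack phantom
#'
#' A ladder of image planes at increasing depth, each carrying random
#' filament textures (anti-aliased line segments with a Gaussian
#' cross-section) plus punctate structures, giving broadband spatial
#' content reminiscent of labelled tissue. Depth is recorded per plane.
#'
#' @param n_planes Number of planes.
#' @param frame_px Frame side length in pixels.
#' @param pixel_nm Pixel pitch in nm.
#' @param z_step_um Axial step between planes in micrometres.
#' @param filament_params List with `n_filaments`, `width_nm`,
#'   `length_um`, `n_puncta`.
#' @param seed RNG seed.
#' @return A list of `phantom` planes with `depth_um` set.
#' @export
make_tissue_stack <- function(n_planes, frame_px, pixel_nm = 65,
                              z_step_um = 0.5,
                              filament_params = list(n_filaments = 30,
                                                     width_nm = 140,
                                                     length_um = 6,
                                                     n_puncta = 150),
                              seed = 1) {
  set.seed(seed)
  fp <- filament_params
  ext <- (frame_px - 1) * pixel_nm
  lapply(seq_len(n_planes), function(i) {
    canvas <- matrix(0, frame_px, frame_px)
    for (f in seq_len(fp$n_filaments)) {
      x0 <- runif(1, 0, ext); y0 <- runif(1, 0, ext)
      th <- runif(1, 0, pi)
      len <- fp$length_um * 1000 * runif(1, 0.4, 1)
      t <- seq(0, len, by = pixel_nm / 2)
      xs <- x0 + cos(th) * t; ys <- y0 + sin(th) * t
      keep <- xs >= 0 & xs <= ext & ys >= 0 & ys <= ext
      if (!any(keep)) next
      # bilinear splat of the sampled polyline
      jj <- xs[keep] / pixel_nm; ii <- ys[keep] / pixel_nm
      j0 <- floor(jj); i0 <- floor(ii); fj <- jj - j0; fi <- ii - i0
      amp <- runif(1, 0.5, 1)
      for (k in seq_along(jj)) {
        i1 <- i0[k] + 1L; j1 <- j0[k] + 1L
        if (i1 >= 1 && i1 < frame_px && j1 >= 1 && j1 < frame_px) {
          canvas[i1, j1] <- canvas[i1, j1] + amp * (1 - fi[k]) * (1 - fj[k])
          canvas[i1 + 1, j1] <- canvas[i1 + 1, j1] + amp * fi[k] * (1 - fj[k])
          canvas[i1, j1 + 1] <- canvas[i1, j1 + 1] + amp * (1 - fi[k]) * fj[k]
          canvas[i1 + 1, j1 + 1] <- canvas[i1 + 1, j1 + 1] + amp * fi[k] * fj[k]
        }
      }
    }
    dens <- conv_tf(canvas, gaussian_tf(frame_px, pixel_nm, fp$width_nm))
    # punctate structures keep the spectrum broadband
    np <- fp$n_puncta
    if (np > 0) {
      idx <- cbind(sample.int(frame_px, np, replace = TRUE),
                   sample.int(frame_px, np, replace = TRUE))
      dens[idx] <- dens[idx] + runif(np, 0.2, 0.6)
    }
    new_phantom(pmax(dens, 0), pixel_nm,
                list(kind = "tissue", plane = i),
                depth_um = (i - 1) * z_step_um)
  })
}
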