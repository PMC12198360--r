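# helper: noise-free single-angle stack plus its analytic band prediction
nf_stack_with_truth <- function(n = 128, p = 350, sample = NULL) {
  optics <- optical_config(frame_px = n)
  lp <- line_profile_2p(optics)
  spec <- line_pattern_spec(p, lp, angles_deg = 0)
  if (is.null(sample)) sample <- make_tissue_stack(1, n, 65, seed = 2)[[1]]
  acq <- acquisition_config(mode = "RS", noise = FALSE)
  stack <- acquire_sim_stack(sample, spec, acq, optics)
  list(optics = optics, spec = spec, sample = sample, stack = stack,
       acq = acq)
}

test_that("per-angle normalization equalises group means exactly", {
  base <- matrix(runif(64^2, 1, 2), 64)
  mk_stack <- function(gains) {
    structure(list(
      frames = lapply(rep(gains, each = 5), function(g) g * base),
      meta = data.frame(angle_deg = rep(c(0, 60, 120), each = 5),
                        phase_index = rep(0:4, 3))), class = "sim_stack")
  }
  stn <- normalize_stack(mk_stack(c(1, 2, 4)))
  means <- tapply(vapply(stn$frames, mean, numeric(1)),
                  stn$meta$angle_deg, mean)
  expect_equal(unname(means / mean(means)), rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  g <- attr(stn, "gains")
  expect_equal(unname(g[1] / g), c(1, 2, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # already equal stack: all gains 1
  expect_equal(unname(attr(normalize_stack(mk_stack(c(1, 1, 1))), "gains")),
               rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  empty <- structure(list(frames = list(),
                          meta = data.frame(angle_deg = numeric(0))),
                     class = "sim_stack")
  expect_error(normalize_stack(empty), "empty")
})

test_that("band separation inverts the synthesis exactly", {
  set.seed(11)
  n <- 64
  # hermitian-consistent bands so the mixed frames are real images:
  # B0 from a real image, B-1 the conjugate mirror of B1
  mirror <- function(M) {
    idx <- c(1, n:2)
    Conj(M[idx, idx])
  }
  B0 <- lilsim:::fft2(matrix(rnorm(n^2), n))
  B1 <- lilsim:::fft2(matrix(rnorm(n^2), n)) +
    1i * lilsim:::fft2(matrix(rnorm(n^2), n))
  Bm1 <- mirror(B1)
  phases <- c(0.1, 1.4, 2.9, 4.0, 5.5)   # deliberately non-equispaced
  frames <- lapply(phases, function(ph) {
    D <- Bm1 * exp(-1i * ph) + B0 + B1 * exp(1i * ph)
    img <- lilsim:::ifft2(D)
    expect_lt(max(abs(Im(img))), 1e-10)
    Re(img)
  })
  got <- separate_bands(frames, phases, 1)
  expect_lt(max(Mod(got[["0"]] - B0)), 1e-9 * max(Mod(B0)))
  expect_lt(max(Mod(got[["1"]] - B1)), 1e-9 * max(Mod(B1)))
  expect_lt(max(Mod(got[["-1"]] - Bm1)), 1e-9 * max(Mod(B1)))
  expect_error(separate_bands(frames, rep(1, 5), 1), "degenerate")
  expect_error(separate_bands(frames[1:2], phases[1:2], 1), "n_phases")
})

test_that("equispaced phases make the pseudo-inverse a scaled DFT", {
  phases <- -2 * pi * (0:4) / 5
  M <- outer(phases, -1:1, function(p, o) exp(1i * o * p))
  pinv <- solve(Conj(t(M)) %*% M, Conj(t(M)))
  dft <- outer(-1:1, phases, function(o, p) exp(-1i * o * p)) / 5
  expect_equal(pinv, dft, tolerance = 1e-12)
})

test_that("separated bands match the analytic forward model", {
  # period commensurate with the frame (no finite-field edge imbalance)
  # and fine enough that the pattern's 4th harmonic -- which 5-phase
  # separation cannot distinguish from the first order -- is negligible
  n <- 128
  p <- n * 65 / 32
  fx <- nf_stack_with_truth(n, p = p)
  frames <- fx$stack$frames
  phases <- -2 * pi * (0:4) / 5
  bands <- separate_bands(frames, phases, 1)
  otf <- detection_otf(fx$optics)
  S <- fx$sample$density * fx$acq$photon_scale
  m1 <- excitation_modulation(fx$spec)
  c0 <- mean(build_pattern(fx$spec, 0, n, 65))
  yg <- matrix(0:(n - 1), n, n) * 65
  pred0 <- c0 * lilsim:::fft2(S) * otf
  pred1 <- m1 * c0 * lilsim:::fft2(S * exp(2i * pi * yg / p)) * otf
  expect_lt(sqrt(sum(Mod(bands[["0"]] - pred0)^2) / sum(Mod(pred0)^2)), 1e-9)
  expect_lt(sqrt(sum(Mod(bands[["1"]] - pred1)^2) / sum(Mod(pred1)^2)), 1e-9)
})

test_that("pattern parameters are recovered from noise-free data", {
  stack <- texture_stack_256()
  optics <- opt256()
  st <- normalize_stack(back_rotate_stack(stack))
  g0 <- st$frames[st$meta$angle_deg == 0]
  est <- estimate_pattern_params(g0, optics)
  expect_equal(est$spacing_nm, 350, tolerance = 0.005 * 350)
  truth <- -2 * pi * (0:4) / 5
  dphi <- ((est$phases - truth + pi) %% (2 * pi)) - pi
  expect_lt(sqrt(mean(dphi^2)) * 180 / pi, 2)
  # equally spaced by 2 pi / 5 within 1 degree
  steps <- diff(est$phases) %% (2 * pi)
  expect_equal(steps * 180 / pi, rep(-72, 4) %% 360, tolerance = 1)
  expect_equal(est$modulation_depth,
               2 * gauss_comb_m1(line_profile_2p(optics)$fwhm_nm, 350),
               tolerance = 0.02)
  expect_equal(est$quality_label, "good")
})

test_that("zero modulation is flagged weak, not an error", {
  optics <- optical_config(frame_px = 128)
  lp <- line_profile_2p(optics)
  spec <- line_pattern_spec(350, lp, angles_deg = 0,
                            polarization_contrast = 0)
  ts <- make_tissue_stack(1, 128, 65, seed = 2)[[1]]
  stack <- acquire_sim_stack(ts, spec,
                             acquisition_config(mode = "RS", noise = FALSE),
                             optics)
  est <- estimate_pattern_params(stack$frames, optics)
  expect_equal(est$quality_label, "weak")
})

test_that("wiener recombination extends support and sharpens a point", {
  n <- 128
  optics <- optical_config(frame_px = n)
  cfg <- recon_config(wiener_w = 1e-6)
  lp <- line_profile_2p(optics)
  p <- 350
  otf <- detection_otf(optics)
  s <- matrix(0, n, n); s[n / 2 + 1, n / 2 + 1] <- 1
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE) * 65
  yg <- matrix(0:(n - 1), n, n) * 65
  phases <- -2 * pi * (0:4) / 5
  m1 <- excitation_modulation(line_pattern_spec(p, lp))
  band_groups <- list(); k_vectors <- list()
  for (th_deg in c(0, 60, 120)) {
    th <- th_deg * pi / 180
    k <- c(cos(th), sin(th)) / p
    u <- xg * cos(th) + yg * sin(th)
    frames <- lapply(0:4, function(j) {
      pat <- 1 + 2 * m1 * cos(2 * pi * (u / p - j / 5))
      lilsim:::conv_tf(s * pat, otf)
    })
    band_groups[[length(band_groups) + 1]] <-
      separate_bands(frames, phases, 1)
    k_vectors[[length(k_vectors) + 1]] <- k
  }
  sim <- wiener_reconstruct(band_groups, k_vectors, rep(2 * m1, 3),
                            optics, cfg)
  kc <- detection_cutoff(optics)
  cutoff <- attr(sim, "cutoff_cyc_nm")
  expect_equal(cutoff, kc + 1 / p, tolerance = 1e-9)
  # spectral support vanishes beyond the extended cutoff
  S2 <- Mod(lilsim:::fft2(sim))
  kr2 <- lilsim:::freq_radius(nrow(sim), attr(sim, "pixel_nm"))
  expect_lt(max(S2[kr2 > cutoff * 1.02]), 1e-6 * max(S2))
  expect_gt(max(S2[kr2 > kc * 1.1 & kr2 < cutoff * 0.9]), 0.05 * max(S2))
  # FWHM shrinks by roughly the support ratio
  wf <- lilsim:::conv_tf(s, otf)
  f_wf <- fwhm_profile(wf[n / 2 + 1, ], 65)$fwhm_nm
  ctr <- which(sim == max(sim), arr.ind = TRUE)[1, ]
  f_sim <- fwhm_profile(sim[ctr[1], ], attr(sim, "pixel_nm"))$fwhm_nm
  ratio <- f_wf / f_sim
  expect_equal(ratio, (kc + 1 / p) / kc, tolerance = 0.12)
  expect_error(wiener_reconstruct(band_groups, list(NULL, NULL, NULL),
                                  rep(1, 3), optics, cfg), "missing")
})

test_that("zero-modulation bands add no resolution beyond the detection support", {
  n <- 128
  optics <- optical_config(frame_px = n)
  otf <- detection_otf(optics)
  s <- matrix(0, n, n); s[n / 2 + 1, n / 2 + 1] <- 1
  frames <- lapply(0:4, function(j) lilsim:::conv_tf(s, otf))  # m = 0
  phases <- -2 * pi * (0:4) / 5
  bands <- separate_bands(frames, phases, 1)
  sim <- wiener_reconstruct(list(bands), list(c(0, 1 / 350)), 0,
                            optics, recon_config(wiener_w = 1e-6))
  S2 <- Mod(lilsim:::fft2(sim))
  kr2 <- lilsim:::freq_radius(nrow(sim), attr(sim, "pixel_nm"))
  kc <- detection_cutoff(optics)
  expect_lt(max(S2[kr2 > kc * 1.05]), 1e-8 * max(S2))
})

test_that("Richardson-Lucy deconvolution conserves flux and sharpens", {
  n <- 128
  optics <- optical_config(frame_px = n)
  psf <- detection_psf(optics)
  xg <- matrix(0:(n - 1), n, n, byrow = TRUE) * 65
  yg <- matrix(0:(n - 1), n, n) * 65
  blob <- exp(-4 * log(2) * ((xg - 64 * 65)^2 + (yg - 64 * 65)^2) / 320^2)
  img <- lilsim:::conv_tf(blob, lilsim:::fft2(psf))
  expect_identical(rl_deconvolve(img, psf, 0L), img)
  widths <- vapply(c(1L, 2L, 4L, 8L), function(it) {
    out <- rl_deconvolve(img, psf, it)
    fwhm_profile(out[65, ], 65)$fwhm_nm
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  out <- rl_deconvolve(img, psf, 20L)
  expect_equal(sum(out), sum(img), tolerance = 1e-3)
  expect_true(all(out >= 0))
  expect_warning(rl_deconvolve(img - 0.1 * max(img), psf, 1L), "clipped")
})

test_that("averaging all frames cancels the imprinted pattern", {
  optics <- optical_config(frame_px = 128)
  us <- make_uniform_slide(128, 1)
  pat <- line_pattern_spec(350, line_profile_2p(optics))
  st <- acquire_sim_stack(us, pat,
                          acquisition_config(mode = "LSS", noise = FALSE),
                          optics)
  stn <- normalize_stack(back_rotate_stack(st))
  avg <- lil2pm_average(stn)
  for (a in c(0, 60, 120)) {
    k <- lilsim:::pattern_k_vector(pat, a)
    expect_lt(modulation_contrast(avg, k, 65), 0.01)
  }
  one <- list(st$frames[[1]])
  expect_identical(lil2pm_average(one), st$frames[[1]])
  expect_equal(lil2pm_average(lapply(stn$frames, `*`, 3)), 3 * avg,
               tolerance = 1e-12)
})

test_that("flat-field correction flattens a uniform acquisition", {
  optics <- optical_config(frame_px = 128)
  us <- make_uniform_slide(128, 1)
  pat <- line_pattern_spec(350, line_profile_2p(optics))
  st <- acquire_sim_stack(us, pat,
                          acquisition_config(mode = "LSS", noise = FALSE),
                          optics)
  stn <- normalize_stack(back_rotate_stack(st))
  avg <- lil2pm_average(stn)
  em <- estimate_excitation_matrix(stn)
  corr <- flat_field_correct(avg, em)
  disk <- disk_mask(128, 8)
  expect_lt(sd(corr[disk]) / mean(corr[disk]), 0.01)
  # constant matrix acts as identity
  expect_equal(flat_field_correct(avg, matrix(1, 128, 128)), avg,
               tolerance = 1e-12, ignore_attr = TRUE)
  bad <- matrix(1, 128, 128); bad[1:3, 1] <- 0
  expect_warning(out <- flat_field_correct(avg, bad), "masked")
  expect_equal(attr(out, "n_masked"), 3L)
  expect_true(all(out[1:3, 1] == 0))
})

test_that("the full pipeline returns all modalities and refuses weak stacks", {
  optics <- opt256()
  lp <- line_profile_2p(optics)
  pat <- line_pattern_spec(350, lp)
  sample <- make_beads(25, 256, 65, seed = 2)
  sample$density <- sample$density + 0.1
  acq <- acquisition_config(mode = "LSS", photon_scale = 300,
                            read_noise_e = 2, seed = 4)
  stack <- acquire_sim_stack(sample, pat, acq, optics)
  rec <- reconstruct(stack, recon_config())
  expect_s3_class(rec, "sim_reconstruction")
  expect_length(rec$estimates, 3)
  expect_false(rec$sim_refused)
  expect_false(is.null(rec$lil2pm))
  expect_null(rec$wil2pm)                     # LSS stack
  expect_equal(nrow(rec$lilsim), 512)
  # determinism: identical stack bytes give identical output
  rec2 <- reconstruct(stack, recon_config())
  expect_identical(rec$lilsim, rec2$lilsim)

  # sub-threshold modulation refuses the SIM output (deep-tissue regime:
  # residual depolarization leaves almost no pattern contrast)
  spec_weak <- line_pattern_spec(350, lp, polarization_contrast = 0.02)
  tissue <- make_tissue_stack(1, 256, 65, seed = 5)[[1]]
  weak <- acquire_sim_stack(tissue, spec_weak, acq, optics)
  expect_warning(recw <- reconstruct(weak, recon_config()), "refused")
  expect_null(recw$lilsim)
  expect_true(recw$sim_refused)
  expect_false(is.null(recw$lil2pm))
})
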