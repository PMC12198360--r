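test_that("lightsheet-shutter timing reproduces the camera arithmetic", {
  acq <- acquisition_config(band_rows = 7, line_exposure_ms = 5)
  t <- lss_timing(acq, 1024)
  expect_equal(t$line_time_ms * 1000, 714.286, tolerance = 1e-3)
  expect_equal(t$total_exposure_ms, 5 + 1023 * 5 / 7, tolerance = 1e-9)
  expect_equal(round(t$total_exposure_ms, 2), 735.71)
  # degenerate single-row frame: total equals the line exposure
  t1 <- lss_timing(acquisition_config(band_rows = 1, line_exposure_ms = 5), 1)
  expect_equal(t1$total_exposure_ms, 5)
})

test_that("exposure-band geometry maps to object space", {
  optics <- optical_config(frame_px = 1024, pixel_nm = 65)
  g <- band_geometry(acquisition_config(band_rows = 7), optics)
  expect_equal(g$length_um, 66.56)
  expect_equal(g$width_nm, 455)
  expect_equal(band_geometry(acquisition_config(band_rows = 1),
                             optics)$width_nm, 65)
})

test_that("acquisition configuration enforces its invariants", {
  expect_error(acquisition_config(band_rows = 4), "odd")
  expect_error(acquisition_config(scatter_fraction = 1), "scatter_fraction")
  expect_error(acquisition_config(photon_scale = 0), "photon_scale")
})

test_that("a zero sample produces pure read noise with zero mean", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p(), angles_deg = 0)
  empty <- make_uniform_slide(128, 0)
  acq <- acquisition_config(mode = "RS", read_noise_e = 2, seed = 3)
  set.seed(3)
  fr <- acquire_frame(empty, 0, 0, acq, optics, pat)
  expect_equal(mean(fr), 0, tolerance = 0.1)
  expect_equal(sd(fr), 2, tolerance = 0.1)
})

test_that("a full-height exposure band degenerates to rolling shutter", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p(), angles_deg = 0)
  ts <- make_tissue_stack(1, 128, 65, seed = 2)[[1]]
  rs <- acquire_frame(ts, 0, 0,
                      acquisition_config(mode = "RS", noise = FALSE),
                      optics, pat)
  expect_warning(
    lss <- acquire_frame(ts, 0, 0,
                         acquisition_config(mode = "LSS", band_rows = 129,
                                            noise = FALSE), optics, pat),
    "degenerates")
  expect_identical(lss, rs)
})

test_that("noise-free rolling shutter equals the pattern-times-sample convolution", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p(), angles_deg = 0)
  us <- make_uniform_slide(128, 2)
  acq <- acquisition_config(mode = "RS", noise = FALSE)
  fr <- acquire_frame(us, 0, 0, acq, optics, pat)
  oracle <- lilsim:::conv_tf(2 * build_pattern(pat, 0, 128, 65),
                             detection_otf(optics)) * acq$photon_scale
  expect_lt(max(abs(fr - oracle)) / max(oracle), 1e-6)
})

test_that("photons are conserved across detection modes", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p(), angles_deg = 0)
  ts <- make_tissue_stack(1, 128, 65, seed = 2)[[1]]
  nf <- function(mode) acquisition_config(mode = mode, noise = FALSE)
  rs <- acquire_frame(ts, 0, 0, nf("RS"), optics, pat)
  pt <- acquire_frame(ts, 0, 0, nf("POINT"), optics, pat)
  lss <- acquire_frame(ts, 0, 0, nf("LSS"), optics, pat)
  expect_equal(sum(rs), sum(pt), tolerance = 1e-9)
  expect_lte(sum(lss), sum(rs))
})

test_that("stacks have the canonical 15-frame order and are seed-deterministic", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p())
  ts <- make_tissue_stack(1, 128, 65, seed = 2)[[1]]
  acq <- acquisition_config(mode = "LSS", photon_scale = 200, seed = 7)
  s1 <- acquire_sim_stack(ts, pat, acq, optics)
  expect_length(s1$frames, 15)
  expect_equal(s1$meta$angle_deg, rep(c(0, 60, 120), each = 5))
  expect_equal(s1$meta$phase_index, rep(0:4, 3))
  expect_true(all(s1$meta$mode == "LSS"))
  s2 <- acquire_sim_stack(ts, pat, acq, optics)
  expect_identical(s1$frames, s2$frames)
})

test_that("phase means agree within Poisson error on a uniform sample", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p(), angles_deg = 0)
  us <- make_uniform_slide(128, 1)
  acq <- acquisition_config(mode = "RS", photon_scale = 100, seed = 2)
  st <- acquire_sim_stack(us, pat, acq, optics)
  means <- vapply(st$frames, mean, numeric(1))
  # each frame mean pools 128^2 Poisson pixels (variance ~ mean electrons)
  sem <- sqrt(mean(means) + acq$read_noise_e^2) / 128
  expect_lt(diff(range(means)), 12 * sem)
})

test_that("the depth model raises the scatter fraction monotonically", {
  acq <- acquisition_config(scatter_length_um = 25)
  expect_equal(lilsim:::scatter_fraction_at(acq, 0), 0)
  z <- seq(0, 80, by = 5)
  f <- vapply(z, function(zz) lilsim:::scatter_fraction_at(acq, zz),
              numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f < 1))
})

test_that("depth stacks apply the depth model and LSS retains more contrast", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p(), angles_deg = 0)
  planes <- make_tissue_stack(6, 128, 65, z_step_um = 6, seed = 4)
  k <- lilsim:::pattern_k_vector(pat, 0)
  res <- list()
  for (m in c("RS", "LSS")) {
    acq <- acquisition_config(mode = m, photon_scale = 300, seed = 9)
    d <- acquire_depth_stack(planes, pat, acq, optics)
    res[[m]] <- vapply(d$frames, function(fr)
      modulation_contrast(fr, k, 65), numeric(1))
  }
  expect_true(all(res$LSS >= res$RS))
  # strong scattering at depth: both clearly below their surface values
  expect_lt(res$RS[6], res$RS[1])
  expect_lt(res$LSS[6], res$LSS[1])
  expect_error(acquire_depth_stack(list(make_uniform_slide(128, 1)),
                                   pat, acquisition_config(), optics),
               "depth metadata")
})

test_that("mismatched sample and optics lattices are rejected", {
  optics <- opt128()
  pat <- line_pattern_spec(350, lp2p(), angles_deg = 0)
  expect_error(acquire_frame(make_uniform_slide(64, 1), 0, 0,
                             acquisition_config(), optics, pat),
               "lattice")
  wrongpx <- make_uniform_slide(128, 1, pixel_nm = 50)
  expect_error(acquire_frame(wrongpx, 0, 0, acquisition_config(),
                             optics, pat), "pitch")
})
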