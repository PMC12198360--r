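test_that("modulation contrast reads a pure sinusoid exactly", {
  n <- 256
  y <- matrix(0:(n - 1), n, n) * 65
  k <- 8 / (n * 65)                       # on-lattice frequency
  img <- 100 * (1 + 0.5 * cos(2 * pi * k * y))
  expect_equal(modulation_contrast(img, c(0, k), 65), 0.5, tolerance = 1e-6)
  expect_lt(modulation_contrast(matrix(7, n, n), c(0, k), 65), 1e-6)
  expect_error(modulation_contrast(img, c(0, 0), 65), "DC")
  expect_error(modulation_contrast(img, c(0, 1 / 100), 65), "Nyquist")
})

test_that("image contrast of a built pattern is twice the harmonic amplitude", {
  spec <- line_pattern_spec(350, lp2p())
  pat <- build_pattern(spec, 0, 256, 65)
  mc <- modulation_contrast(pat, c(0, 1 / 350), 65)
  expect_equal(mc, 2 * excitation_modulation(spec), tolerance = 0.01)
})

test_that("the reconstructability floor is a strict threshold", {
  expect_true(reconstructable(0.2))
  expect_false(reconstructable(0.07))
  expect_false(reconstructable(0.1))       # boundary: strictly above
  expect_true(reconstructable(0.05, threshold = 0.01))
})

test_that("SBR and SNR follow their definitions", {
  img <- matrix(2, 20, 20)
  sm <- matrix(FALSE, 20, 20); sm[1:5, ] <- TRUE
  bm <- matrix(FALSE, 20, 20); bm[10:20, ] <- TRUE
  img[sm] <- 10
  expect_warning(r <- sbr_snr(img, sm, bm), "infinite")
  expect_equal(r$sbr, 5)
  expect_equal(r$snr, Inf)
  expect_error(sbr_snr(img, sm, sm), "disjoint")
  expect_error(sbr_snr(img, matrix(FALSE, 20, 20), bm), "non-empty")
  # Poisson statistics: snr of a lambda = 100 field is about sqrt(100)
  set.seed(8)
  pf <- matrix(rpois(10000, 100), 100)
  sm2 <- matrix(TRUE, 100, 100); sm2[1, 1] <- FALSE
  bm2 <- matrix(FALSE, 100, 100); bm2[1, 1] <- TRUE
  r2 <- sbr_snr(pf, sm2, bm2)
  expect_equal(r2$snr, 10, tolerance = 0.05)
})

test_that("Gaussian FWHM fitting recovers a known width", {
  x <- (0:40) * 65
  prof <- 5 + 80 * exp(-4 * log(2) * (x - 1300)^2 / 275^2)
  r <- fwhm_profile(prof, 65)
  expect_equal(r$status, "ok")
  expect_equal(r$fwhm_nm, 275, tolerance = 0.02 * 275)
  # single-pixel impulse is undersampled
  imp <- rep(0, 41); imp[21] <- 1
  expect_false(fwhm_profile(imp, 65)$status == "ok")
  # pure noise yields a failure status and no number
  set.seed(2)
  rn <- fwhm_profile(rnorm(41), 65)
  expect_false(rn$status == "ok")
  expect_true(is.na(rn$fwhm_nm))
})

test_that("half-maximum width reads a flat-top profile's physical width", {
  x <- (0:40) * 32.5
  prof <- ifelse(abs(x - 650) <= 95, 1, 0) + 0.01
  r <- fwhm_halfmax(prof, 32.5)
  expect_equal(r$status, "ok")
  expect_equal(r$fwhm_nm, 190, tolerance = 35)
})

test_that("line-pair resolvability follows the dip criterion", {
  x <- (0:199) * 20
  two <- function(gap, fw = 150) {
    c1 <- 2000 - gap / 2; c2 <- 2000 + gap / 2
    exp(-4 * log(2) * (x - c1)^2 / fw^2) +
      exp(-4 * log(2) * (x - c2)^2 / fw^2)
  }
  pos <- function(gap) matrix(c(2000 - gap / 2, 2000 + gap / 2), 1)
  expect_true(line_pair_resolved(two(450), pos(450), 20))
  expect_false(line_pair_resolved(two(0), pos(0), 20))
  # monotone over the ladder: once unresolved, smaller gaps stay so
  gaps <- seq(390, 150, by = -30)
  res <- vapply(gaps, function(g)
    line_pair_resolved(two(g), pos(g), 20), logical(1))
  expect_true(all(diff(as.integer(res)) <= 0))
})

test_that("FRC handles degenerate inputs and locates a band limit", {
  set.seed(5)
  n <- 128
  img <- matrix(rnorm(n^2), n)
  same <- frc_resolution(img, img, 65)
  expect_equal(same$status, "beyond_nyquist")
  expect_true(is.na(same$resolution_nm))
  # independent noise decorrelates at every ring
  ind <- frc_resolution(matrix(rnorm(n^2), n), matrix(rnorm(n^2), n), 65)
  expect_lt(mean(abs(ind$frc)), 0.1)
  # band-limited object plus noise: threshold crossing near the band limit
  optics <- optical_config(frame_px = n)
  otf <- detection_otf(optics)
  obj <- lilsim:::conv_tf(matrix(rpois(n^2, 30), n), otf)
  est <- vapply(1:10, function(i) {
    a <- obj + matrix(rnorm(n^2, 0, 0.1 * sd(obj)), n)
    b <- obj + matrix(rnorm(n^2, 0, 0.1 * sd(obj)), n)
    frc_resolution(a, b, 65)$resolution_nm
  }, numeric(1))
  expect_equal(median(est), 1 / detection_cutoff(optics), tolerance = 0.1)
})

test_that("decorrelation analysis locates a known spectral cutoff", {
  set.seed(9)
  n <- 256
  optics <- optical_config(frame_px = n)
  otf <- detection_otf(optics)
  img <- lilsim:::conv_tf(matrix(rpois(n^2, 50), n), otf)
  d <- decorrelation_resolution(img, 65)
  expect_equal(d$status, "ok")
  expect_equal(d$resolution_nm, 1 / detection_cutoff(optics),
               tolerance = 0.05)
  # invariant to global intensity scaling
  d2 <- decorrelation_resolution(img * 1000, 65)
  expect_equal(d$resolution_nm, d2$resolution_nm, tolerance = 1e-9)
  # white noise has no significant spectral edge
  wn <- decorrelation_resolution(matrix(rnorm(n^2), n), 65)
  expect_equal(wn$status, "failed")
  expect_true(is.na(wn$resolution_nm))
})

test_that("FRC and decorrelation agree on the same reconstruction", {
  set.seed(4)
  n <- 128
  optics <- optical_config(frame_px = n)
  otf <- detection_otf(optics)
  obj <- lilsim:::conv_tf(matrix(rpois(n^2, 50), n), otf)
  a <- obj + matrix(rnorm(n^2, 0, 0.08 * sd(obj)), n)
  b <- obj + matrix(rnorm(n^2, 0, 0.08 * sd(obj)), n)
  rf <- frc_resolution(a, b, 65)$resolution_nm
  rd <- decorrelation_resolution(a, 65)$resolution_nm
  expect_equal(rf, rd, tolerance = 0.2)
})
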