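# Shared fixtures, generated in code and cached across tests.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

opt128 <- function() fixture("opt128", function() optical_config(frame_px = 128))
opt256 <- function() fixture("opt256", function() optical_config(frame_px = 256))
lp2p <- function() fixture("lp2p", function() line_profile_2p(opt128()))

disk_mask <- function(n, margin_px = 8) {
  c0 <- (n + 1) / 2
  d2 <- outer(((1:n) - c0)^2, ((1:n) - c0)^2, "+")
  d2 <= ((n - 1) / 2 - margin_px)^2
}

# noise-free textured stack used by the parameter-recovery tests
texture_stack_256 <- function() fixture("texture_stack_256", function() {
  optics <- opt256()
  pat <- line_pattern_spec(350, line_profile_2p(optics))
  ts <- make_tissue_stack(1, 256, 65, seed = 9)[[1]]
  acq <- acquisition_config(mode = "RS", noise = FALSE)
  acquire_sim_stack(ts, pat, acq, optics)
})

# Gaussian comb first-harmonic amplitude, closed form
gauss_comb_m1 <- function(fwhm2p_nm, spacing_nm) {
  exp(-pi^2 * fwhm2p_nm^2 / (4 * log(2) * spacing_nm^2))
}
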