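# lilsim

Simulation and reconstruction for super-resolution structured
illumination microscopy (SIM) built from a **sequentially scanned
two-photon excitation line** with camera detection in rolling-shutter
(RS) or lightsheet-shutter (LSS) mode.

## Who this is for

Microscopists and method developers who want to study — entirely in
silico — how line-scanning two-photon SIM behaves: how much resolution
the sequential pattern can gain over the diffraction-limited image, how
the camera's lightsheet shutter preserves the detected modulation
contrast in scattering tissue, and how the standard SIM processing
chain (back rotation, band separation, generalized Wiener filtering,
Richardson–Lucy deconvolution) performs on such data. Everything runs
on synthetic phantoms generated in code; no data downloads are needed.

## The model in brief

The excitation pattern of period `p` is built line by line from a
two-photon line focus (effective profile = squared one-photon profile;
Gaussian FWHM `0.5·λ_ex/NA/√2 ≈ 190 nm` at NA 1.49, 800 nm). Its
first-harmonic excitation modulation

    m₁(p) = exp(−π² w² / (4 ln2 · p²)),   w = 2P line FWHM,

decays as `p` approaches the diffraction limit, unlike interference
patterns (`m = 1`). Fifteen raw frames (3 pattern orientations set by a
Dove-prism field rotator, optical angle = 2 × mechanical angle, × 5
phases) are separated into frequency bands

    D_i(f) = Σ_o e^{i o φ_i} · c_o · S(f − o k) H(f),

shifted back, and recombined by a generalized Wiener filter with OTF
attenuation and triangle apodization to the extended cutoff
`k_c + |k_p|`, `k_c = 2NA/λ_em`. Reconstruction is refused when the
detected modulation contrast falls below the 0.1 floor. Resolution and
contrast are quantified by bead-FWHM analysis, Fourier ring correlation
(0.143 threshold) and image decorrelation analysis.

## Worked example

```r
library(lilsim)

optics  <- optical_config(frame_px = 256)           # NA 1.49, 65 nm px
pattern <- line_pattern_spec(350, line_profile_2p(optics))
sample  <- make_beads(25, optics$frame_px, optics$pixel_nm, seed = 2)
acq     <- acquisition_config(mode = "LSS", photon_scale = 300,
                              read_noise_e = 2, seed = 4)

stack <- acquire_sim_stack(sample, pattern, acq, optics)
rec   <- reconstruct(stack, recon_config())
rec
#> SIM reconstruction
#>   angle   90.0 deg: spacing 349.9 nm, m = 0.889 (good)
#>   angle   30.0 deg: spacing 349.9 nm, m = 0.852 (good)
#>   angle  150.0 deg: spacing 350.1 nm, m = 0.834 (good)
#>   super-resolved image: 512 px, cutoff 0.00793 cycles/nm

resolution_report(rec$lil2pm, rec$lilsim,
                  pixel_ref_nm = optics$pixel_nm,
                  centers_nm = sample$ground_truth$centers_nm)
#> Resolution report
#>   reference decorrelation resolution: 236 nm
#>   SIM decorrelation resolution: 127 nm (improvement 1.86x)
#>   reference bead FWHM: 230 +/- 6 nm (n = 48)
#>   SIM bead FWHM: 189 +/- 15 nm (n = 50)
```

The estimated pattern spacing (350 nm), orientations (the three optical
angles mapped into the common sample frame) and modulation depths are
recovered from the raw frames alone; the super-resolved image halves
the decorrelation resolution of the pattern-averaged reference, and the
measured bead FWHM drops from 230 nm to about the true 190 nm bead
size. The camera timing model reproduces the lightsheet-shutter
arithmetic exactly:

```r
t <- lss_timing(acq, 1024)
sprintf("line time %.3f us, full frame %.2f ms",
        t$line_time_ms * 1000, t$total_exposure_ms)
#> "line time 714.286 us, full frame 735.71 ms"
```

Other entry points worth knowing: `exp_depth_series()` (RS-vs-LSS
modulation contrast against imaging depth in scattering tissue),
`exp_bead_chain()` (FWHM across the four processing variants),
`exp_improvement_bound()` (the theoretical resolution-gain sweep), and
`write_sim_stack()` / `read_sim_stack()` for TIFF round trips.

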