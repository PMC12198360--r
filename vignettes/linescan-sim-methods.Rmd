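---
title: "Line-scanning two-photon SIM: models, reconstruction and metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line-scanning two-photon SIM: models, reconstruction and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lilsim)
```

# The imaging model

`lilsim` simulates and reconstructs structured illumination microscopy
(SIM) in which the excitation pattern is not formed by beam interference
but built up line by line: a two-photon excitation line focus is stepped
across the sample with a period `p`, and a camera records the emission
either in rolling-shutter mode (RS, effectively full-frame integration)
or in lightsheet-shutter mode (LSS), where only a narrow band of rows
co-moving with the line is exposed. Because the two-photon signal is
proportional to the squared excitation intensity, the effective line
profile is the square of the one-photon line profile; for the default
Gaussian model with one-photon FWHM `0.5 * lambda_ex / NA`
(268 nm at NA 1.49 and 800 nm) the two-photon line FWHM is
`268 / sqrt(2) = 190 nm`.

Sequential pattern build-up has one decisive consequence: the
excitation modulation of the pattern's first harmonic,
`m1(p) = |P1|/P0 = exp(-pi^2 w^2 / (4 log 2 p^2))` for a Gaussian line
of FWHM `w`, decays as the pattern period `p` shrinks, whereas
interference patterns stay fully modulated up to the coherent cutoff.
This trades ultimate resolution gain for compatibility with the
lightsheet shutter, which rejects scattered emission from neighbouring
lines and thereby preserves the *detected* modulation contrast deep in
scattering tissue.

Conventions used throughout: images are matrices with row index `y`
(the scan axis, increasing downwards) and column index `x`; pixel
`(i, j)` sits at `((j-1) px, (i-1) px)` nm; frequencies are in
cycles/nm with FFT layout (DC at `[1, 1]`); rotations are
counterclockwise in the displayed orientation. A pattern at optical
angle 0 has lines along rows, so its frequency vector points along +y;
an optical rotation by `theta` moves it to `90 - theta` degrees from
the +x axis. The Dove-prism field rotator maps a mechanical angle
`alpha` to an optical rotation `2 alpha` (30 degrees mechanical for the
canonical 60 degree pattern rotation).

# The forward simulator

`acquire_frame()` implements, per scan line at position `y_j`:
emission `= blur( rotate(sample) * lineprofile^2(y - y_j) )`, where the
blur is the ideal incoherent detection OTF at the band-centre emission
wavelength (587.5 nm for the 525-650 nm band; the cutoff is
`k_c = 2 NA / lambda`, a minimum resolvable period of 197 nm). The
emission is split into a ballistic fraction `1 - f` and a scattered
fraction `f` convolved with a wide Gaussian halo (default FWHM 3 um —
the physical halo shape in tissue is unknown, an isotropic Gaussian is
the conventional neutral choice). RS accumulates every line over the
whole frame; LSS accumulates only the rows within the exposure band
(default 7 rows = 455 nm at 65 nm pixels, wider than one pattern period
so the dark regions between lines — where the super-resolution
information lives — are retained); POINT integrates each line into a
single row as the point-detector reference. Poisson noise on the
accumulated photo-electrons plus Gaussian read noise completes the
camera model, one seeded RNG stream per stack.

Depth-dependent scattering uses `f(z) = 1 - exp(-z / l_s)`. No
quantitative scattering law is claimed by the method itself; we chose
`l_s = 25 um` a priori from the analytic contrast model (the RS
contrast `m0 (1 - f)` falls to the 0.1 reconstructability floor near
`1 l_s`, the LSS contrast near `2.4 l_s` for a surface contrast of
~0.25 and a band/halo acceptance of ~0.15), which emulates the
qualitative behaviour of interest: both curves decay monotonically with
depth, LSS always retains at least the RS contrast, and the RS curve
loses reconstructability tens of micrometres before LSS. Absolute
depth-contrast values are sample-specific and are not asserted
anywhere.

An optional `system_blur_fwhm_nm` adds a scalar Gaussian blur to the
detected emission, modelling the gap between the as-built system PSF
and the design PSF (residual aberrations, index mismatch). Processing
always assumes the design OTF. The bead-chain experiment
(`exp_bead_chain()`) uses 160 nm, calibrated so that the simulated
pattern-averaged bead FWHM lands near the ~275 nm that real systems
report for 190 nm beads instead of the ideal ~205 nm — without this
mismatch, Richardson-Lucy deconvolution of raw frames with the exact
PSF on a dark background is an inverse crime that sharpens far beyond
what any real system achieves.

# Reconstruction chain

`reconstruct()` runs the four canonical steps in order: digital back
rotation of every frame into the common sample frame (bilinear
resampling about the frame centre, zero fill outside, all quantitative
metrics evaluated on the inscribed disk), per-angle brightness
normalization to the global mean, SIM computation, and optional
flat-field correction.

Pattern estimation (`estimate_pattern_params()`) locates the pattern
frequency by *normalised* cross-correlation of the separated first-order
band against the zero band over the OTF overlap: both bands carry the
same object spectrum, so the correlation coefficient approaches one
exactly at the true shift; the per-shift overlap normalisation is what
makes the statistic robust — unnormalised correlation is confounded by
the object's own spectral speckle. A two-stage zoomed DFT refines the
peak to sub-lattice precision (noise-free accuracy better than 0.1% in
`|k|`). Per-frame phases come from a widefield-weighted matched filter
at the refined frequency; the phase-independent zero-band offset and
the conjugate-band term are fitted out iteratively, leaving noise-free
phase errors below 2 degrees. The modulation depth is the complex
ratio of the shifted first-order band to the zero band on the
OTF-weighted overlap (`m = 2 |a|`). Estimates are labelled `good`
(`m >= 0.3`), `usable` (`m >= 0.1`) or `weak`; a `weak` label is also
assigned when the correlation peak is insignificant or the fitted
phases stray more than 25 degrees RMS from the equidistant ladder the
scanner produces by construction. One known limitation: a field of only
a handful of point emitters has an everywhere-correlated spectrum (a
sum of a few phasors), which makes frequency estimation ill-posed; such
data are flagged rather than estimated, and calibration fields of a few
tens of beads or extended textures are used for parameter estimation.

Band separation solves the `n_phases x (2 order + 1)` linear system by
pseudo-inverse; with five equally spaced phases this reduces to scaled
DFT rows, and the second pattern harmonic cancels exactly (one reason
five phases beat three). The default separation order is 1: near-limit
patterns carry negligible second-harmonic power. Note an intrinsic
aliasing of phase-stepped separation: harmonic `-4` is
phase-indistinguishable from order `+1` under five phases; for the
default Gaussian line its relative amplitude `exp(-15 pi^2 w^2/(4 log 2
p^2))` is below 1e-7 at practically relevant spacings.

The generalised Wiener recombination shifts each band to its true
position with an exact subpixel phase ramp on a 2x upsampled lattice
(the extended spectrum would alias on the acquisition lattice),
equalises first orders by `m/2`, and combines
`sum(conj(H_o) B_o) / (sum(|H_o|^2) + w^2)` with OTF attenuation
`A(k) = 1 - a exp(-k^2 / 2 sigma^2)` (defaults `a = 0.990`, FWHM 1.20
cycles/um — the FWHM is in cycles per micrometre, following the
convention of the reconstruction software that popularised these
defaults) applied to the zero band, and a triangle apodization to the
extended cutoff `k_c + |k_p|`. The Wiener parameter `w^2 = 0.05` is our
default for noisy data; negative output values are retained in the
stored float image. Richardson-Lucy deconvolution (10-50 iterations)
is available both for raw frames and, with the triangle-apodization
PSF, for the reconstructed image. If any angle's estimated modulation
falls below the 0.1 floor — below which separation artifacts degrade
the result — the super-resolved output is refused with a warning and
only the pattern-averaged image is returned.

Flat-field correction divides by a unit-mean excitation matrix
estimated from a uniform-slide acquisition, smoothed with a Gaussian of
4 px FWHM: wide enough to reject shot noise, and well below the beat
period of the lightsheet-shutter band-clipping stripes, which are a
systematic detection effect the correction must retain and remove.

# Quantification

* `modulation_contrast()` returns `2 |F(k_peak)| / |F(0)|` from a
  Hann-windowed, mean-subtracted zoomed DFT, so a pure
  `b (1 + m cos)` image returns `m` exactly; the 0.1
  reconstructability floor refers to this normalisation, and the
  threshold comparison is strict (`> 0.1`). The image-domain contrast
  of a built pattern is exactly twice the excitation harmonic amplitude
  `m1`.
* `sbr_snr()` implements `mean(signal)/mean(background)` and
  `mean(signal)/sd(signal)`; the alternative reading (noise from the
  background) is exposed via `noise_from`.
* `fwhm_profile()` is a Gaussian fit with guards (undersampled,
  no significant peak, runaway width); `fwhm_halfmax()` reads the
  physical half-maximum width, appropriate for deconvolved flat-top
  bead profiles whose diameter a Gaussian fit underestimates (a perfect
  190 nm disk Gauss-fits to roughly 161 nm).
* `frc_resolution()` correlates two independent-noise realizations
  over one-bin Fourier rings and reads the resolution at the fixed
  0.143 threshold by linear interpolation.
* `decorrelation_resolution()` estimates a single image's effective
  cutoff from `d(r) = sum_{|f|<=r} |I| / (||I|| sqrt(N_r))` over a
  ladder of high-pass pre-filters; the highest significant local
  maximum marks the cutoff. Candidates whose curve does not fall
  clearly below its peak by Nyquist are rejected (noise-dominated
  curves keep rising), and filtered curves retaining negligible energy
  are skipped so windowing leakage cannot spoof a peak. The ring count
  scales with the lattice (four rings per bin), keeping quantisation
  bias of the located edge below one percent.
* `line_pair_resolved()` applies the dip criterion (valley at most 0.8
  of the weaker peak; the factor is our choice) to line-pair ladders
  from 390 nm down to 150 nm in 30 nm steps.

# The canned experiments and their design choices

`exp_improvement_bound()` reproduces the theoretical resolution-gain
analysis: a noise-free point target is imaged through 15-frame stacks
(3 angles x 5 phases) while the pattern spacing is swept downward in
10 nm steps from 400 nm on a 512 px frame. For sequential patterns the
sweep stops when the excitation modulation `m1` no longer exceeds the
0.1 floor (at the default optics: 240 nm spacing); for interference
patterns (`m = 1`) the final step is placed exactly at the detection
cutoff. Patterns are synthesised at each orientation directly in the
sample frame and the reconstruction receives the known parameters: the
experiment quantifies the optical bound, not estimator robustness, and
at the floor the *detected* modulation is ~0.02, far below the gate
that `reconstruct()` would apply to measured data. Resolution is
measured by decorrelation analysis with edge apodization disabled (the
point-target fields decay to zero at the borders; a window would smear
the spectral edge) and with the reference measured on the same 2x
lattice as the SIM output so the estimator's fixed edge smear cancels
in the ratio; the Wiener regularisation is set to 1e-6, matched to the
noise-free data, so the weak outer band edges are not suppressed. At
the defaults the sequential sweep measures a maximum factor of 1.81
(support ratio 1.82 at the floor) against 2.00 for the coherent
reference — sequential pattern build-up gives away roughly a tenth of
the coherent gain in exchange for deep-tissue robustness.

`exp_depth_series()` pairs RS and LSS acquisitions of the same tissue
phantoms with the same noise seeds over a depth ladder and reports both
modulation-contrast curves and their 0.1 crossings. `exp_bead_chain()`
compares the four processing variants on a 190 nm bead field
(pattern-averaged, RL of the raw frames then averaged, SIM without
deconvolution, SIM with deconvolution); its study conditions — 25
beads, uniform background at 0.1 of the bead density, photon scale 300
e-, read noise 2 e-, system blur 160 nm, 10 RL iterations — are chosen
to emulate a realistic calibration measurement as discussed above, and
its widths are half-maximum readings.

# What the phantoms do and do not emulate

The generator produces bead fields with sub-pixel centres (4x
supersampled rasterization), line-pair calibration targets
(390 to 150 nm gaps), uniform slides, and tissue-like depth stacks of
random filaments plus puncta with broadband spectra. All phantoms are
deterministic in (parameters, seed). They emulate the *spatial
statistics* needed by the pipeline, not real tissue optics: there is no
refractive-index heterogeneity, no depth-varying aberration, no
photobleaching, and the scattering model is a single-parameter
exponential with an isotropic halo. Passing tests therefore demonstrate
the correctness and internal consistency of the simulation and
reconstruction chain and the qualitative physics of shutter-mode
contrast retention — not quantitative agreement with any particular
specimen; measured depth-contrast values on real samples depend
strongly on the specimen and instrument.

# Problem sizes

The test suite runs phantom and reconstruction checks at 64-256 px and
the improvement-bound sweep at the experiment's native 512 px; the
depth series uses nine planes at 4 um steps with five paired noise
repetitions per depth, a ladder deep enough that the monotone decay of
the median curves is well resolved against the residual Monte Carlo
error. These sizes are the package's reference configurations; every
experiment accepts larger frames and finer ladders unchanged.
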