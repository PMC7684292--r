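---
title: "Methods: quantifying retinal redox state, layer thickness and function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying retinal redox state, layer thickness and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinodex)
```

retinodex implements the quantitative readouts used to evaluate retinal
degeneration and its response to photobiomodulation (PBM) in rodent models
of retinitis pigmentosa: mitochondrial redox imaging, SD-OCT layer
morphometry, electroretinography, and photoreceptor-row histomorphometry.
This vignette explains the models behind each pipeline, the parameters that
matter, the phantom generator the package validates itself against, and the
numerical choices made where the underlying protocols leave the operator
freedom.

## The cryo-fluorescence redox pipeline

Mitochondrial metabolic state can be read out from the autofluorescence of
two endogenous coenzymes: NADH (reduced, excited near 336 nm, emitting near
450 nm) and FAD (oxidized, 470/520 nm). Their intensity ratio NADH/FAD —
the redox ratio (RR) — falls when the respiratory chain shifts toward the
oxidized state, as happens under chronic proteotoxic stress in the
degenerating retina. In cryo-imaging, a frozen eye is sectioned at 10 µm
while a camera captures a fluorescence image per slice per channel, giving
two aligned 3D stacks (~400 slices for a ~4 mm eye).

The pipeline is:

1. **Voxelwise ratio** (`compute_redox_volume()`): RR(v) = NADH(v)/FAD(v)
   wherever FAD(v) is above a floor. The floor (default 1% of the FAD
   channel's Otsu threshold, so it scales with the data) exists purely to
   keep near-zero FAD voxels from producing unbounded ratios; in practice
   it excludes nothing inside tissue.
2. **Shell segmentation** (`segment_shell()`): the retina is a sphere-like
   shell of bright tissue. We threshold the summed NADH + FAD intensity
   with Otsu's method, apply one slice-wise morphological closing to
   consolidate connectivity across noise-induced gaps, and keep the largest
   3D connected component, restricted to supra-threshold voxels. The
   restriction matters: closing alone would annex sub-threshold background
   voxels whose ratio is near background-NADH/background-FAD ≈ 1,
   contaminating the projection.
3. **Maximum intensity projection** (`max_project()`): each (x, y) pixel
   takes the maximum masked ratio along z. MIP is the standard display and
   analysis reduction for this modality because every part of the curved
   anatomy contributes to the 2D image.
4. **Mean redox ratio** (`mean_redox()`): the mean of the projected image.
   The frame-mean convention (sum over all Nx × Ny pixels divided by
   Nx × Ny, background counting zero) is implemented as
   `scope = "full_frame"`; the default `scope = "foreground"` averages
   over pixels backed by at least one retinal voxel. Representative group
   means of 0.66–0.97 are only consistent with foreground averaging — a
   frame mean dilutes toward zero as the field of view grows around the
   eye — so foreground is the default and the frame mean is retained for
   literal conformance with the printed formula.
5. **Oxidative shift** (`oxidative_shift()`):
   `100 · (RR_ref − RR_test)/RR_ref`, the percent oxidation of a test
   group relative to a reference. For the representative dystrophic
   (0.66) and control (0.92) means this is 28%.

### What the projection does to noise

The maximum of n noisy samples sits above their mean by roughly
`σ·Φ⁻¹(1 − 1/(n+1))`. A projection column crossing the shell twice
contributes tens of voxels; tangential columns at the shell rim contribute
up to ~100. At a voxel coefficient of variation of 0.02 per channel the
projected mean therefore sits ~2σ of the ratio noise (≈ 0.05 at RR 0.92)
above the configured tissue ratio, and the bias grows with noise. This is
a property of max projection itself, not of the implementation; the test
suite asserts it directly (projected mean ≥ configured ratio,
nondecreasing in noise), and it is the reason recovery tests on noisy
phantoms sit slightly above the configured ratio while zero-noise phantoms
recover it exactly.

## The cryo phantom

`make_cryo_phantom()` draws a centred spherical shell (the retina) inside a
cubic voxel grid: shell voxels are `Normal(channel_mean, cv·channel_mean)`
truncated at zero, background likewise around a dim background mean, all
randomness from one explicit seed (the global RNG stream is untouched).
The packaged profiles (`cryo_phantom_profile()`) use a 2 mm eye at 10 µm
voxels — 200³ voxels, a desk-scale stand-in for the ~4 mm rat eye — with
shell outer radius 900 µm and thickness 90 µm, preserving the real
thickness-to-radius proportion (~180 µm retina on a ~2 mm-radius eye).
Channel expectations 92:100, 66:100 and 97:100 reproduce the
representative control, dystrophic and PBM-treated group ratios.

The phantom emulates what the analysis assumes — a bright shell with
stationary multiplicative noise — and nothing it does not: no optical
point-spread, no attenuation with depth, no anatomical asymmetry, no
cryogenic quantum-yield effects. Passing recovery tests therefore show the
*pipeline arithmetic* is right, not that the instrument model is complete.

## SD-OCT longitudinal reflectivity profiles

A B-scan is a matrix of A-scans (columns) by axial depth (rows). Retinal
layers alternate in reflectivity — synaptic/plexiform layers bright,
nuclear layers dark — so a depth profile averaged over a lateral window
(the longitudinal reflectivity profile, LRP; `compute_lrp()`, default
width 100 px) shows three bright bands: the inner retinal complex, the
outer plexiform layer (OPL), and the IS/OS-to-RPE complex, with the outer
nuclear layer (ONL) as the deep trough between the last two.

`detect_boundaries()` places interfaces at half-height crossings of the
profile (midpoint of profile min and max), linearly interpolated to
sub-pixel depth: the ILM at the first rising edge, Bruch's membrane (BM)
at the last falling edge, and the ONL limits at the falling/rising edges
around the deep trough. Half-height edges are used because the source
protocols specify only the low/high reflectivity correspondence, not an
edge operator; they make thickness estimates exactly invariant under
global intensity scaling, and on noiseless phantoms they recover
interfaces to within half an axial pixel (exactly, when an interface falls
on a pixel boundary, thanks to partial-volume mixing in the generator).

Thickness protocols follow the standard sampling scheme:
`total_retinal_thickness()` averages BM − ILM over 10 LRPs, 5 locations
50 px apart on each side of the optic nerve head (ONH);
`onl_thickness_profile()` reports ONL thickness at ±88, ±176, ±264, ±352
and ±440 µm from the ONH. The default lateral scale of 1.76 µm/px makes
these two schemes coincide (50 px ≡ 88 µm); the instrument conversion is
not part of the protocol, so it is an explicit parameter everywhere. The
ONH column is taken as input (it is a manual landmark in practice; the
phantom provides it), and offsets in µm are mapped to columns by rounding.

`register_and_average()` aligns repeated B-scans to the first by the
integer shift maximizing FFT cross-correlation of the demeaned images and
averages pixelwise — 40–80 repeats reduce speckle by √n, which is what
makes half-height edges stable at speckle CV 0.1. The OCT phantom
(`make_oct_bscan()`) uses piecewise-constant bands with multiplicative
Gaussian speckle, CV-parameterized for variance control; true OCT speckle
is Rayleigh-like, a deliberate simplification. Packaged profiles configure
ILM-to-BM spans of 178.1 µm (treated) and 169.2 µm (sham) at p30.

## ERG quantification

`measure_amplitudes()` applies the standard clinical conventions: baseline
is the mean over the 20 ms before the flash; the a-wave (photoreceptor)
amplitude is baseline minus the trough within 50 ms post-flash; the b-wave
(bipolar/Müller) amplitude is the following peak measured from the a-wave
trough; implicit times are the extremum times. Because the raw minimum of
a noisy trace is an extreme-value statistic biased downward, a
Savitzky–Golay filter (order 3, 9 samples) precedes peak picking by
default; it preserves quadratic extrema, keeps noiseless recovery errors
below 1%, and holds the mean recovery error below 3% at noise of 5% of
the a-wave amplitude (`smooth = FALSE` disables it). An a-wave is reported
as zero unless the deflection exceeds twice the baseline noise SD.
`flicker_amplitude()` folds the trace into the 30 Hz stimulus period,
averages cycles, and reports peak-to-trough of the averaged cycle.

The ERG generator (`make_erg_trace()`) is a biphasic model: a negative
Gaussian lobe at the a-wave implicit time and a positive lobe at the
b-wave time, with amplitudes following the Naka–Rushton saturating
intensity–response function `A(I) = A_max·Iⁿ/(Iⁿ + Kⁿ)` — the standard
monotone saturating form, chosen because it gives a closed-form recovery
oracle. Amplitude parameters use measurement conventions (a: baseline to
trough; b: trough to peak), so configured and recovered values are
directly comparable. Defaults: a 150 µV, b 300 µV, implicit times
15/60 ms, widths 8/12 ms, K = 1000 mcd·s/m², n = 1, 1 kHz sampling, flash
series 100–25,000 mcd·s/m². The real protocol's amplifier band-pass is
not modelled; amplitudes on recorded data depend on it.

## Histomorphometry

`count_rows()` counts rows of photoreceptor nuclei in a binary ONL mask:
the vertical occupancy profile over a column window is thresholded at 50%
of the window width and maximal occupied runs are counted. This is an
operationalization of manual row counting chosen so the phantom truth
(`make_onl_mask()`: stacked rows of ellipses at touching pitch, so band
height = rows × nucleus diameter) is exactly recoverable; segmenting
nuclei in real micrographs is out of scope. `build_spider()` assembles
counts at ±100/200/300 µm from the ONH into the conventional
superior-to-inferior spider profile.

## Dose arithmetic and statistics

`energy_density()` converts irradiance and duration to the J/cm² dose
(25 mW/cm² × 180 s = 4.5 J/cm²). `group_summary()` reports per-group
mean ± SE and, on request, a Welch two-sample comparison; the mixed-model
machinery used for longitudinal animal statistics is deliberately out of
scope — those analyses belong to off-the-shelf tools, and the phantom
studies here need only means, SEs and two-group contrasts.

## Worked example

```{r, eval = FALSE}
ph <- make_cryo_phantom(cryo_phantom_profile("P23H", seed = 1))
res <- run_redox_pipeline(ph$nadh, ph$fad)
glance(res)
autoplot(res)

sd_ph <- make_cryo_phantom(cryo_phantom_profile("SD", seed = 1))
sd_res <- run_redox_pipeline(sd_ph$nadh, sd_ph$fad)
oxidative_shift(res$mean_rr, sd_res$mean_rr)
```

## Problem sizes and determinism

The packaged cryo profiles are 200³ voxels (~8·10⁶ per channel) and run
the full pipeline in ~10 s each; OCT recovery uses 40 replicate
1000 × 300 B-scans per group; module tests use 60³ volumes and 320-column
scans, which exercise identical code paths. All generators take one seed
per call and restore the caller's RNG state; identical configurations are
bit-identical. Errors are classified (`retinodex_input_error`,
`retinodex_analysis_error`) and the pipeline wrapper tags them with the
stage that raised them.

## Known limitations

- The MIP mean is upward-biased under noise (see above); comparisons
  between groups imaged at the same noise level are unaffected, absolute
  ratios are not.
- The shell segmentation stands in for an unpublished prior method; it is
  validated by Dice overlap against phantom truth, not against the
  original code.
- The OCT boundary caller assumes the three-bright-band LRP morphology
  and will (by design) refuse profiles where disease has collapsed the
  banding.
- Phantoms model noise, not optics: no PSF, attenuation, shadowing, or
  Rayleigh speckle statistics.
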