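# retinodex

Quantification stack for studies of retinal degeneration and
photobiomodulation in rodent models of retinitis pigmentosa. The package
implements, as tested R pipelines:

- **3D cryo-fluorescence redox imaging** — voxelwise NADH/FAD ratio,
  segmentation of the sphere-like retinal shell, maximum intensity
  projection (MIP) along z, and the mean redox ratio

  Mean = (1/(Nx·Ny)) Σᵢ Σⱼ eye_Maxpro(i, j)

  (frame-mean convention; the default averages over retina-backed
  pixels), plus the between-group oxidative shift
  100·(RR_ref − RR_test)/RR_ref;
- **SD-OCT morphometry** — B-scan registration/averaging, longitudinal
  reflectivity profiles (LRP), half-height layer-boundary detection (ILM,
  OPL/ONL, ONL/IS-OS, Bruch's membrane), total retinal thickness at 5
  locations 50 px apart on either side of the optic nerve head, and ONL
  thickness at ±88–440 µm;
- **ERG quantification** — a-/b-wave amplitudes and implicit times by
  ISCEV conventions, scotopic intensity series, and 30 Hz flicker
  amplitude by cycle folding;
- **Histomorphometry** — photoreceptor nuclei-row counts and
  superior–inferior spider profiles;
- **Seeded phantom generators** for all four modalities with known ground
  truth (shell masks, layer depths, closed-form ERG amplitudes, row
  counts), used throughout the test suite for parameter-recovery
  validation;
- light-dose arithmetic (irradiance × duration → J/cm²) and per-group
  mean ± SE summaries with Welch comparisons.

Results are tibble-friendly: fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Generate the dystrophic (P23H) and control (SD) cryo phantoms and run the
full redox pipeline:

```r
library(retinodex)

p23h <- make_cryo_phantom(cryo_phantom_profile("P23H", seed = 1))
res  <- run_redox_pipeline(p23h$nadh, p23h$fad)
res
#> <redox_summary> mean RR 0.699 +/- 0.0001 (SE), 25448 foreground px, scope = foreground

sd  <- make_cryo_phantom(cryo_phantom_profile("SD", seed = 1))
ctl <- run_redox_pipeline(sd$nadh, sd$fad)
oxidative_shift(res$mean_rr, ctl$mean_rr)
#> [1] 28.26087
```

The dystrophic phantom (configured tissue ratio 0.66) is recovered at
0.699 and the control (0.92) at 0.974: max projection of a noisy volume
sits ~2σ of the voxel noise above the tissue ratio (see the methods
vignette), but the bias is proportional, so the oxidative shift — the
group-comparison statistic — comes out at 28.3%, the same value the
configured means give by hand (100·(0.92 − 0.66)/0.92 = 28.26).

OCT thickness from 40 registered-and-averaged speckled B-scans:

```r
set40 <- make_oct_scan_set(oct_phantom_profile("PBM-p30", seed = 1), 40)
avg   <- register_and_average(set40$bscans)
total_retinal_thickness(avg)
#> [1] 177.9545   # configured ILM-to-BM span: 178.1 um

tidy(detect_boundaries(compute_lrp(avg, 750, 100)))
#> # A tibble: 4 × 2
#>   boundary depth_um
#> 1 ilm          20.1
#> 2 opl_onl     125.
#> 3 onl_isos     165.
#> 4 bm           198.
```

ERG amplitudes at 10,000 mcd·s/m²:

```r
measure_amplitudes(make_erg_trace(erg_phantom_config(), 10000))
#> <erg_amplitudes> a: 136.1 uV @ 15 ms | b: 272.5 uV @ 60 ms
```

(closed-form expectations at this intensity: a 136.4 µV, b 272.7 µV).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/retinodex.R` (`simulate`, `redox`, `oct`, `erg`, `histo`
subcommands; exit codes 0/2/3 for success/input error/analysis error).

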