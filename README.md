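# ricsbind

Raster image correlation spectroscopy (RICS) analysis of
transcription-factor binding in live nuclei.

## What it is for

A pioneer transcription factor tagged with GFP is imaged together with a
histone marker (RFP) on a point-scanning confocal. A single raster-scanned
frame already contains temporal information: adjacent pixels are
microseconds apart, adjacent lines milliseconds apart. `ricsbind` turns
two-channel raster-scan movies into per-time-point concentration pools of
the factor:

* total nuclear concentration `C_tot` — from the amplitude `A` of the 2D
  spatial autocorrelation function (ACF), since `A = γ/N̄` with `N̄` the
  mean number of molecules in the illumination volume of the point spread
  function (PSF);
* immobile fraction `φ` — the weight of the zero-diffusivity component in
  the two-component ACF model
  `G = A[φ·G_imm + (1−φ)·G_dif(D)] + B`, fitted in the field's standard
  two-step procedure (amplitude from the fast-axis Gaussian cut, then
  mobility with `A` held fixed);
* active (chromatin-correlated) fraction `ψ = A_cc / A_red` — from the
  two-color cross-correlation (ccRICS) amplitude against the histone
  channel, with lateral PSF displacements fitted and the axial
  displacement calibrated from bead z-stacks;
* diffusivity `D` of the free pool (µm²/s).

Downstream, the pools feed a thermodynamic equilibrium binding model
(Hill occupancy per site class, `C_bound = C_B·C^n/(K_D^n + C^n)`, plus an
optional power-law site capacity `C_B = a·C_free^k` for factors that open
their own sites), a molecular-brightness / detector S-factor analysis with
brightness-drift corrections, and Smoluchowski residence-time estimates
(`k_on = 4πDba`, `τ = 1/(k_on·K_D)`).

Everything is testable without microscope data: the package ships a
Brownian-dynamics raster-scan simulator (`simulate_timeseries()`,
`simulate_bead_stack()`) that renders free, quasi-immobile and co-bound
particles through a 3D Gaussian PSF with analog detector noise and known
ground truth.

Audience: quantitative imaging groups doing fluorescence fluctuation
spectroscopy in nuclei (fly embryos and beyond) and method developers who
need a fully synthetic, ground-truthed RICS test bed.

## Worked example

Simulate a 30-frame, 256×256 two-channel movie at a realistic scan timing
(pixel 31.95 nm, dwell 2.06 µs, line 4.94 ms) with known truth — total
concentration 30 nM, immobile fraction 0.5, co-bound fraction 0.3,
D = 2 µm²/s — and run the full chain:

```r
library(ricsbind)
res <- run_full_pipeline(default_run_config(seed = 1))
res$records[, c("time_s", "C_tot_nM", "phi", "psi", "D_um2_s")]
#>    time_s C_tot_nM       phi       psi  D_um2_s
#> 1  6.3232 29.93540 0.5694221 0.3352129 2.980221
#> 2 18.9696 30.87436 0.3609386 0.2777346 1.364192
#> 3 31.6160 29.60135 0.5079524 0.3570795 1.697962
```

Each row is one group of 10 frames (the movie's three analysis groups):
the recovered total concentration sits within a few percent of the 30 nM
truth, the immobile fraction scatters around 0.5 and the co-bound fraction
around 0.3 — single-group mobility estimates are intrinsically noisy at
this problem size, which is why downstream summaries aggregate groups and
seeds. `res$brightness` holds the matching apparent-brightness records.

Interpreting concentrations as binding:

```r
# accessible-site concentration: 12,135 sites, 435 µm^3 nucleus, diploid
sites_concentration(12135, 435, ploidy = 2)
#> [1] 92.64759   # nM

# residence time from the Smoluchowski on-rate at D = 2 µm²/s
kon <- smoluchowski_kon(D_um2_s = 2, b_nm = 0.34, a = 0.2)
residence_time(KD_nM = 20, kon = kon)
#> [1] 48.58344   # seconds
```

A shell entry point for batch runs:

```sh
Rscript scripts/run_pipeline.R --seed 1 --out runs/demo --write-tiff
```

## Package tour

| Area | Functions |
| --- | --- |
| Geometry & PSF | `scan_geometry()`, `psf_model()`, `psf_pair()`, `line_time_from_frame()` |
| Simulation | `sim_truth()`, `recovery_truth()`, `simulate_timeseries()`, `simulate_particle_paths()`, `render_raster_frame()`, `simulate_bead_stack()`, `write_movie_tiff()` |
| Preprocessing | `estimate_background()`, `plan_frame_groups()`, `segment_nuclei()`, `detrend_frames()`, `make_frame_groups()` |
| Correlation | `masked_correlation_2d()`, `direct_correlation_oracle()`, `average_group_correlation()`, `subtract_surface_baseline()` |
| Model fitting | `rics_kernel()`, `fit_fast_axis()`, `fit_two_component()`, `fit_ccf()`, `compute_psi()`, `amplitude_to_concentration()`, `fit_bead_3d()`, `axial_displacement_factor()`, `pool_record()` |
| Brightness | `apparent_brightness()`, `shot_noise()`, `estimate_s_factor()`, `molecular_brightness()`, `normalize_brightness()`, `brightness_correction()` |
| Binding model | `hill_bound()`, `power_law_sites()`, `solve_free_concentration()`, `fit_equilibrium_model()`, `sites_concentration()`, `accessible_sites_timecourse()`, `kd_from_occupancy()`, `smoluchowski_kon()`, `residence_time()` |
| Orchestration | `default_run_config()`, `run_full_pipeline()`, `analyze_movie()`, `analyze_group()` |

The methods vignette (`vignettes/rics-tf-binding.Rmd`) documents the
models, the estimator conventions, the simulator's assumptions and the
numerical choices in detail.
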