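---
title: "Measuring transcription-factor binding by raster image correlation spectroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring transcription-factor binding by raster image correlation spectroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricsbind)
```

## The measurement problem

A pioneer transcription factor (TF) such as Zelda or GAGA factor is
present in the nucleus as a mixture of pools: molecules diffusing freely,
molecules bound to chromatin in transcriptionally engaged ("active")
regions, and molecules immobilized elsewhere. Bulk fluorescence reports
only the total. `ricsbind` implements an analysis chain that separates
these pools from a single two-channel confocal raster-scan time series — a
GFP-tagged TF in the green channel and a histone marker (His2Av-RFP-like)
in the red channel — with no single-molecule tracking.

The chain exploits the time structure hidden in a raster scan: adjacent
pixels along a line are microseconds apart (pixel dwell $\tau_p$), adjacent
lines are milliseconds apart (line period $\tau_\ell$). The spatial
autocorrelation function (ACF) of the image therefore mixes spatial and
temporal correlations, and its decay along the two lag axes encodes
diffusion, while its amplitude encodes absolute concentration. This is
raster image correlation spectroscopy (RICS); the two-color
cross-correlation variant (ccRICS) adds the chromatin-correlated fraction.

## The model

For a species of diffusivity $D$ observed through a 3D Gaussian point
spread function (lateral $1/e^2$ radius $w_0$, axial radius $w_z$), the
normalized raster-scan ACF at pixel lag $(\Delta x, \Delta y)$ is

$$G_n(\Delta x, \Delta y) =
  \left(1 + \frac{4D\tau}{w_0^2}\right)^{-1}
  \left(1 + \frac{4D\tau}{w_z^2}\right)^{-1/2}
  \exp\!\left(-\frac{\Delta r^2(\Delta x^2 + \Delta y^2)/w_0^2}
                    {1 + 4D\tau/w_0^2}\right),
  \qquad \tau = |\tau_p \Delta x + \tau_\ell \Delta y|,$$

with pixel size $\Delta r$ (`rics_kernel()`). At $D = 0$ this reduces to
the pure PSF Gaussian — the immobile kernel. The measured surface is
modeled as an amplitude times a linear combination of an immobile and a
diffusing kernel,

$$G(\Delta x, \Delta y) = A\,[\varphi\,G_{\mathrm{imm}} +
  (1-\varphi)\,G_{\mathrm{dif}}(D)] + B,$$

where $\varphi$ is the immobile fraction and $B$ a small background
constant. Fitting proceeds in two steps, as is standard for RICS:

1. **Amplitude step** (`fit_fast_axis()`): the fast-axis cut
   $G(\Delta x, 0)$ is fit with $A e^{-\Delta r^2 \Delta x^2 / w_0^2} + B$,
   with $(0,0)$ excluded (it carries the full shot noise), $|B| < 10^{-3}$
   and $w_0$ allowed to vary by ±30% around its configured value. Along
   this cut the diffusion factors are negligible ($\tau_p$ is microseconds),
   so every mobility class contributes its full amplitude.
2. **Mobility step** (`fit_two_component()`): holding $A$ fixed, the 2D
   surface is fit for $(\varphi, D, B)$ by bounded least squares with
   deterministic multistarts ($D \in [0.01, 100]\ \mu m^2/s$,
   $\varphi \in [0,1]$); the best residual wins and ties go to the smallest
   $D$.

### From amplitude to concentration

The fitted amplitude obeys $A = \gamma/\bar N$ with
$\gamma = 2^{-3/2}$ for a 3D Gaussian and $\bar N$ the mean number of
molecules in the illumination-weighted sampling volume
$\int W = \gamma\,\pi^{3/2} w_0^2 w_z$. The concentration is therefore

$$C = \frac{\bar N}{N_A\,\gamma\,V_{PSF}} = \frac{1}{A\,N_A\,\pi^{3/2} w_0^2 w_z},$$

which is independent of the shape-factor convention
(`amplitude_to_concentration()` reports $\bar N$, both volumes and $C$).
This pairing of $\bar N = \gamma/A$ with the sampling volume
$\gamma V_{PSF}$ — rather than with $V_{PSF}$ itself — is forced by
self-consistency: a direct calculation for the Gaussian PSF gives
$G(0) = 1/(C\,\pi^{3/2} w_0^2 w_z)$, and the package's simulator recovers
the true simulated concentration only under this convention. The
mismatched pairing would under-report every concentration by exactly
$\gamma \approx 0.354$.

### The chromatin-correlated fraction

The cross-correlation surface between the TF and histone channels is fit
with a displaced immobile kernel (the co-bound pool is
chromatin-associated; a diffusive cross term is available via the
`cross_D` argument):

$$G_{cc} = A_{cc} \exp\!\left(-\frac{(\Delta r \Delta x - \Delta x_0)^2 +
  (\Delta r \Delta y - \Delta y_0)^2}{w_{0,avg}^2}\right) + B,
  \qquad w_{0,avg}^2 = \tfrac{1}{2}(w_{0,g}^2 + w_{0,r}^2).$$

The lateral PSF displacements $\Delta x_0, \Delta y_0$ are free fit
parameters; the axial displacement $\Delta z_0$ is calibrated once from
bead z-stacks (`simulate_bead_stack()` + `fit_bead_3d()`) and enters as a
multiplicative amplitude factor
$\exp(2\Delta z_0^2/(w_{z,g}^2 + w_{z,r}^2))$
(`axial_displacement_factor()`); at a typical calibration it is ≈1.02 and
barely matters. The exact constant in that exponent (2 versus 4) is an
open modeling choice; the adopted form is 1 at zero offset, monotone in
$|\Delta z_0|$, and reproduces the near-unity calibrated values, and its
entire effect on $\psi$ is a ≤2% scale factor. The active fraction is then

$$\psi = A_{cc} / A_{red},$$

clipped to $[0,1]$ (`compute_psi()`). With matched per-channel effective
volumes this ratio equals the co-moving fraction exactly; with mismatched
PSFs it acquires a volume-ratio factor
$\left[\int W_g W_r \int W_r\right] / \left[\int W_r^2 \int W_g\right]$
(about +13% for a 10% larger red PSF), which is why `psf_pair()` defaults
to matched channels and why an instrument-matched configuration should
calibrate the PSFs per channel.

### Concentration pools

Each frame group yields a `PoolRecord` (`pool_record()`):
$C_{imm} = \varphi C_{tot}$, $C_{act} = \psi C_{tot}$,
$C_{inact} = (\varphi - \psi) C_{tot}$, $C_{free} = (1-\varphi) C_{tot}$.
When a noisy group produces $\psi > \varphi$ the record is flagged and the
inactive pool reported as 0 rather than negative.

## Preprocessing

Raw movies pass through four stages (`make_frame_groups()`):

* **Grouping**: consecutive, non-overlapping groups of 7–12 frames
  (default 10). A trailing remainder below 7 borrows frames from earlier
  groups (25 frames → 10, 8, 7); when no legal split exists the remainder
  merges into the final group.
* **Background**: the pixel histogram of the group-average frame is
  modeled as a ≤2-component Gaussian mixture and the low mode's center is
  subtracted (`estimate_background()`); estimating on the average rather
  than per member reduces noise. The low mode's width, re-estimated on a
  single member frame (where detector noise is not averaged down), serves
  as the zero-intensity variance of the brightness analysis.
* **Segmentation** (`segment_nuclei()`): Gaussian smoothing (σ = 2 px) →
  Otsu threshold → distance transform → watershed with an h-maxima-style
  tolerance (10% of the distance maximum) → minimum area 500 px → 2 px
  mask erosion to keep steep nuclear-edge gradients out of the
  correlation. The mask from the group average is used for every member
  frame.
* **Detrend** (`detrend_frames()`): each member frame has the group
  average subtracted pixelwise and the scalar nuclear mean added back, so
  structure immobile over the whole group is removed while species that
  move or exchange within the group survive. The added-back scalar is the
  mean over the nuclear mask: it is the mean the correlation estimator
  normalizes by, so using the whole-frame mean would silently rescale
  every amplitude.

## The masked correlation estimator

`masked_correlation_2d()` computes
$G(\Delta) = \langle \delta I_a \delta I_b \rangle_\Delta /
(\langle I_a\rangle \langle I_b\rangle)$ over pixel pairs that both lie in
the nuclear mask, via zero-padded FFTs of the masked fluctuation images
normalized per lag by the mask's own autocorrelation (the exact pair
count). This equals the literal double sum for arbitrary mask shapes;
`direct_correlation_oracle()` is that double sum, kept as an independent
oracle, and the test suite checks agreement to $10^{-10}$ on random masked
inputs. Surfaces are computed per labeled nucleus and per frame, then
averaged (`average_group_correlation()`); lag bins supported by fewer than
100 pixel pairs are set to missing. For auto pairs the $\Delta y < 0$
half-plane is redundant and omitted; cross surfaces keep it because the
channel displacement breaks the symmetry.

**Finite-mask baseline.** Removing the sample mask mean biases every lag
bin downward by roughly (total correlation mass)/(mask area). For a
nucleus of a few thousand pixels this pedestal is a few times $10^{-3}$ —
comparable to the $|B| \le 10^{-3}$ constraint of the amplitude fit — and
it varies slowly across the lag plane. `subtract_surface_baseline()`
estimates it on the far-lag annulus (Chebyshev radius ≥ 24 px, where the
kernels retain <0.2% of their amplitude) and removes it before fitting;
the analysis then keeps the tight $B$ bound for the amplitude step and a
looser $5\times10^{-3}$ bound for the 2D fits, whose residual baseline
structure is larger. The mobility fit is further restricted to
$|\Delta x| \le 24$, $\Delta y \le 16$ (`fit_window`): diffusion
information is concentrated in the first ~16 line lags, while the far bins
carry mostly residual large-scale structure from confined motion
surviving the detrend.

## Brightness analysis

For an analog photodetector the noise variance is proportional to the
mean, $\sigma^2_{shot} = S\,I$. The chain
(`apparent_brightness()` → `shot_noise()` → `estimate_s_factor()` →
`molecular_brightness()`) measures the apparent brightness
$B = (\sigma^2 - \sigma_0^2)/I$ of the nuclear pixels, subtracts the
particle-fluctuation variance $A I^2$ known from the ACF amplitude,
regresses the remaining shot noise on intensity to obtain $S$ (with a free
intercept $b$ for robustness — it absorbs, e.g., offset-driven noise),
and converts to molecular brightness $Q = (B - S)/S$.

When the label's brightness changes over time (maturation, aggregation),
amplitudes overcount molecules. The two-level correction
(`normalize_brightness()` + `brightness_correction()`) designates a
reference window, sets $Q_{min}$ to the maximum $Q$ inside it, computes
$q(t) = \max(Q(t)/Q_{min}, 1)$ and divides $A$ and $\varphi$ by $q$; with
$q = 1$ everything is untouched. The $Q(B, S)$ and $A_{new}, \varphi_{new}$
conventions adopted here — $(B-S)/S$ and division by $q$ — satisfy the
defining properties (identity at $q=1$, corrections only ever reduce the
apparent values, pool relationships preserved); each lives in a one-line
function so an alternative convention is a local change.

## The equilibrium binding model

With pools in hand, binding is modeled thermodynamically. Occupancy of a
site class with capacity $C_B$ and dissociation constant $K_D$ follows the
Hill form $C_{bound} = C_B C^n/(K_D^n + C^n)$ (`hill_bound()`; $n = 1$
throughout except a sigmoidal inactive pool, where $n = 2$). Conservation

$$C_{tot} = C_{free} + C_{act}(C_{free}) + C_{inact}(C_{free})$$

is strictly increasing in $C_{free}$, so `solve_free_concentration()`
inverts it by vectorized bisection on $[0, C_{tot}]$ (60 halvings; the
conservation identity holds to well below $10^{-9}$ nM).
`fit_equilibrium_model()` estimates $(K_{D,a}, C_{B,a}, K_{D,i}, C_{B,i})$
by multistart bounded least squares on the active and inactive records,
after dropping short cycles (cycle 10) and the first
`drop_first = 2` records of each cycle, where equilibrium is not yet
established (the count is unreported in the field; 2 is this package's
default and configurable).

For a pioneer factor that opens its own sites, the active capacity is not
constant: `power_law_sites()` models it as $C_B = a\,C_{free}^k$. Two
practical notes from the package's recovery experiments, both visible in
the test suite:

* Fitting $(K_{D,a}, a, k)$ jointly is poorly identified — the effective
  log-log slope of the active curve is $k + K_D/(K_D + C)$, so the
  exponent and the dissociation constant trade off. The `fix_pl_k`
  argument holds $k$ at a separately calibrated value (the
  accessible-sites relation), which restores identifiability.
* When records span decades, absolute least squares is dominated by the
  largest concentrations; `weights = "relative"` divides residuals by the
  observations and is the right choice for multiplicative errors.

Helper calculators close the loop with printed observables:
`sites_concentration()` (a site count over a nuclear volume, with
ploidy), `kd_from_occupancy()` (single-point $K_D$ back-out),
`accessible_sites_timecourse()` (inverting the $n=1$ Hill model per time
point; per-cycle nuclear volumes are user-supplied config since only one
cycle's volume is commonly known, and the site counts are accordingly
approximate), and the kinetic pair `smoluchowski_kon()` /
`residence_time()` ($k_{on} = 4\pi D b a$, $\tau = 1/(k_{on} K_D)$).

## The simulator: what it emulates and what it does not

Every stage above is exercised against `simulate_timeseries()`, a
Brownian-dynamics raster-scan renderer with known ground truth:

* **Scan timing.** Particle positions advance once per image line
  ($\tau_\ell \approx 5$ ms), not per pixel: a $D = 2\ \mu m^2/s$ particle
  moves <0.15 px within a line, so the fast-axis decay is carried by the
  PSF, exactly as the fitted model assumes.
* **Species.** Free particles take Gaussian steps of per-axis variance
  $2D\tau_\ell$, specularly reflected at the disk boundary and the axial
  box edges — reflection, not rejection: rejection freezes particles in a
  boundary shell one step wide and measurably depresses the fitted
  diffusivity. Quasi-immobile binders hold position and relocate to a
  uniformly drawn point in their nucleus at rate $k_{off}$ (unbind, fast
  rebind at a new site); co-bound particles are single particles rendered
  in both channels, so their green/red fluctuations are coherent by
  construction. The explicit two-state mobility model (bound ↔ free at
  $k_{on}, k_{off}$) is available in `simulate_particle_paths()`.
* **Why $k_{off} = 1/\text{frame time}$.** The moving-average detrend
  retains the fraction $1 - \frac{1}{n^2}\sum_{i,j}
  e^{-k_{off}\,\Delta t\,|i-j|}$ of a binder's ACF amplitude for an
  $n$-frame group. Binders much slower than the group duration are
  removed with the static structure (retention → 0); binders faster than
  the ~0.16 s correlation window blur within a frame. At
  $k_{off} = 1/\text{frame time}$ and $n = 10$ the retention is ≈0.80
  with within-window decay under 12% — immobile on the ACF's timescale,
  alive on the detrend's. This is the default the recovery experiments
  are run at.
* **Detector.** Analog shot noise: Gaussian with variance
  $S_{true} \times$ mean (default $S_{true} = 400$), a constant offset
  $b_0$ (default 3000 counts; the instrument's offset handling is
  configuration, not physics), and 16-bit quantization. Default particle
  brightness (1000 counts/dwell) puts the molecular brightness near
  $Q \approx 0.8$, typical of a bright fluorescent-protein fusion, and
  keeps the offset more than 2.5 noise standard deviations above zero so
  clipping is negligible.
* **Geometry.** Disk nuclei on a grid; the default recovery phantom uses
  six nuclei of 40 px radius in a 256×256 field (≈46% coverage), which
  keeps the background histogram mode well resolved, provides six
  independent nuclear regions to average confined-diffusion modes over,
  and limits the confinement bias on the fitted diffusivity. Particles
  occupy $|z| \le 2\ \mu m$, covering >99% of the axial PSF mass.

Not simulated: photobleaching, triplet blinking, mitotic chromosome
dynamics, nuclear import/export, embryo-scale geometry or nuclear-cycle
structure (cycle labels are metadata supplied alongside the movie). A
passing recovery suite therefore demonstrates that the estimators are
consistent for the stated statistical model of the data — not that real
embryo movies satisfy that model.

## Recovery performance and problem sizes

The test suite runs the full chain on 30-frame, 256×256 two-channel
movies at the reference scan timing ($\Delta r = 31.95$ nm,
$\tau_p = 2.06\ \mu s$, $\tau_\ell = 4.94$ ms), with truth
$C_{tot} = 30$ nM, $\varphi = 0.5$, $\psi = 0.3$, $D = 2\ \mu m^2/s$,
three analysis groups per movie, medians over five seeds. Under these
conditions the chain recovers $C$ within 20%, $\varphi$ within 0.1,
$\psi$ within 0.05 and $D$ within 25%. The residual biases are real
properties of the method at this scale: the detrend removes part of the
bound-pool amplitude (inflating $C$ slightly), nuclear confinement
depresses the apparent $D$, and the $(\varphi, D)$ pair is weakly
identified on single groups — the per-group scatter in $\varphi$ is
visibly larger than the seed-median error. Binding-model recovery uses 30
synthetic records at 5% multiplicative noise; parameter errors stay
within 25% for the Hill case.

## Numerical choices and degenerate inputs

* All nonlinear fits are bounded Levenberg–Marquardt (`minpack.lm`), with
  deterministic staggered-grid multistarts (8 for the surface fits, 20
  log-uniform draws for the equilibrium model); ties in the two-component
  fit go to the smallest $D$.
* Fit weights are uniform across lag bins; $(0,0)$ is excluded for auto
  surfaces and included for the cross surface (the two detectors' shot
  noise is independent).
* An amplitude below 3× the far-lag noise floor is flagged (auto) or set
  to zero (cross: "no detectable co-binding").
* Flagged red-channel amplitudes propagate `NA` into $\psi$; empty masks
  skip the group with a warning; movies shorter than 7 frames, overlapping
  nuclei, beads closer than $3 w_0$ and negative rates are rejected.
* Seeds are explicit everywhere; identical seeds give byte-identical CSV
  outputs.

## Limitations

* Concentrations inherit the PSF calibration: a 10% error in $w_0$ is a
  ~20% error in $C$. Bead-based calibration of $w_0, w_z$ per channel is
  assumed done upstream.
* $\psi = A_{cc}/A_{red}$ assumes matched effective volumes (see above).
* The immobile/diffusing decomposition is a two-state idealization; slow
  subdiffusive mixtures will load partly on each component.
* Site-count conversions assume the supplied nuclear volumes and uniform
  accessibility; they are order-of-magnitude estimates by design.
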