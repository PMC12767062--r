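---
title: "Methods: ECS rheology from single-particle tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECS rheology from single-particle tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecsrheomap)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic tests do and do not show about
real data.

## The measurement problem

Nanoparticle probes diffusing in the brain extracellular space (ECS)
report its local geometry and viscosity. Around amyloid plaques the ECS is
remodeled: a dense cellular ring surrounds the fibrillar core, and probe
motion changes between the outer parenchyma (Out), the ring (Ring), and
the core (Amyloid). Two probe classes are analysed: quantum dots (QDs,
~30 nm, imaged at 28 Hz) for compartment-level rheology, and elongated
near-infrared nanotube probes (33 ms/frame) whose transverse excursions
report the local ECS channel width at nanometre scale.

## MSD rheology

For a trajectory sampled at interval Δt, the time-averaged MSD at frame
lag k uses **all ordered pairs** (overlapping windows). Overlap maximises
the information extracted from short tracks — only trajectories with more
than 10 points (≥ 11) are analysed, so many tracks barely clear that bar.
`compute_msd()` is tested for exact equality against an O(n²) brute-force
double loop.

- **D_inst** (`fit_dinst()`): OLS line with *free intercept* through the
  first 4 MSD points; D = slope/4. The free intercept absorbs the static
  localization-noise offset 4Δx², standard SPT practice; without it, noise
  would inflate D by Δx²/Δt. Negative fitted slopes are floored at 0 and
  flagged (they classify immobile).
- **Confinement area** (`confinement_area()`): unweighted mean of MSD
  values with lag in the closed window [0.6, 0.8] s — at 28 Hz the frame
  lags 17–22 (0.607–0.786 s). "Between 0.6 and 0.8 s" is read literally as
  a closed interval. Per-trajectory confinement is only reported when the
  trajectory spans at least 0.8 s.
- **Mobility** (`classify_mobility()`): immobile iff
  D_inst < 0.005 µm²/s, *strictly* — a trajectory at exactly the
  threshold is mobile ("lower than"). `immobile_fraction()` applies the
  field-of-view rule: FOVs whose Amyloid ROI contains no immobile particle
  are dropped from all compartments of that analysis; plaque-free FOVs
  (no Amyloid records) are untouched.
- **Relative change** (`relative_change()`):
  100·(x−y)/(0.5·(x+y)) with x the outermost compartment value. Published
  per-compartment summaries are ambiguous about the sign convention (a
  lower inner value gives a *positive* change under this ordering, yet
  negative medians are sometimes reported for the same comparison), so
  both orderings are exposed via the `order` argument rather than guessing.

The analytic anchor for confinement: for independent uniform points
P₁, P₂ in a disk of radius R, E|P₁−P₂|² = R². A particle equilibrated in a
reflecting disk therefore shows an MSD plateau of exactly R², which the
simulator reproduces and the tests verify against a Monte-Carlo oracle.

**Stationarity caveat.** The plateau identity needs the window to lie in
the stationary regime: the disk mixing time is ≈ R²/(4D). Simulations
validating the plateau use D = 0.15 µm²/s (top of the physiological
regime) for R ≈ 0.3 µm, and scale D with R² for other radii — a numerical
validation condition, not a claim about QD diffusivity.

## Localization and linking

- **Detection** (`detect_spots()`): à-trous B3-spline wavelet band at
  scale 2, thresholded at k × robust noise SD (1.4826·MAD), local maxima
  of surviving regions of ≥ 3 px. The wavelet family and scale of the
  original commercial software are unspecified; the detector is
  parameterised instead of matched.
- **Localization** (`fit_gaussian()`): least-squares isotropic 2D Gaussian
  (amplitude, sub-pixel centre, σ, offset) on a 7×7 window; fits with σ
  outside [0.5, 5] px or non-convergence are rejected with a reason.
  Coordinates: pixel centres at integer indices from 0, origin top-left,
  x along columns; all analysis in µm.
- **Linking** (`link_trajectories()`): globally optimal frame-to-frame
  assignment (Jonker–Volgenant shortest augmenting paths) minimising total
  squared displacement, with unmatched endpoints allowed at cost
  max_disp². This replaces the stochastic simulated-annealing reconnection
  of the original software with a deterministic, testable equivalent —
  tests verify equality of total cost with exhaustive enumeration on all
  small instances. Gap closing (default off) joins track ends to later
  starts. Ties cannot occur in exact arithmetic; the implementation is
  deterministic throughout.
- **Trajectory filter**: ≥ 11 points ("more than 10", read strictly).
- **Precision** (`estimate_precision()`): SD of the coordinates of an
  immobile emitter (~50 frames); σ_mean = (σ_x + σ_y)/2. The immobility
  precondition uses the *median windowed* D (10-frame sliding windows):
  a single global 4-point fit is dominated by the noise floor Δx²/t and
  would misclassify jittery immobile emitters.

## Nanotube local analysis

- **Local D** (`sliding_dinst()`): 10-frame sliding windows (stride 1),
  3-point MSD fit with free intercept, D = slope/4 floored at 0. The
  *median* of this estimator over windows is inherently 11–14% below the
  true D (the per-window estimate is right-skewed; its mean is unbiased) —
  recovery tests therefore use the ±15% band appropriate for a median
  statistic of this estimator.
- **Immobile exclusion** (`exclude_immobile()`): plateau-shaped global MSD
  (late/early ratio < 2) or global D below 0.005 µm²/s.
- **Eccentricity** (`window_eccentricity()`): for each 6-point window,
  ecc = √(λ_major/λ_minor) of the position covariance, λ_minor floored at
  Δx² for stability; collinear windows flag an infinite sentinel.
  `select_max_confinement()` takes the earliest maximum finite value.
- **Local width** (`estimate_local_width()`): uniform transverse occupancy
  across a channel of width w gives transverse variance w²/12, so
  w = √(12·max(σ²_minor − Δx², 0)) after quadrature subtraction of the
  localization variance; σ below Δx flags "below resolution".

**Width estimation design.** Six points are too few for a stable variance
once an extreme-statistic window has been singled out: selecting the
maximum-eccentricity window among ~95 overlapping windows pins the
selected minor variance at or below the noise floor regardless of the
true width (60–140 nm), and ~80% of trajectories would flag below
resolution. The package therefore uses the 6-point window to *locate*
maximal confinement and measures the transverse variance over the
24-point neighbourhood centred on it (`width_window` in `local_map()`).
The residual downward bias is absorbed by a **one-time multiplicative
calibration factor, 1.2334**, the mean truth/raw-median ratio over channel
simulations at 60/78/100/140 nm (D = 0.04 µm²/s longitudinal, 33 ms
frames, 100-frame trajectories, Δx = 30 nm; reproducible via
`calibrate_width_estimator()`). The factor is stored in the package and
never refit per dataset. With it, median recovery is within 20% at all
four widths. The exact width estimator of the original nanotube-tracking
work is not public; this uniform-occupancy estimator with simulation
calibration is a declared substitute, and parity with original maps is
not claimed.

- **Error model** (`dinst_error()`): ΔD_inst = Δx²/t with t the fit-window
  duration; 30 nm and 3 × 30 ms give 0.01 µm²/s exactly.

## Plaque geometry and morphometry

- ROIs: core radius r = √(A/π); ring width 1.82·r (the median
  ring-width/core-radius ratio of cortical plaques); Out annulus to twice
  the ring outer radius by default (unstated upstream; recorded in
  outputs). Mask-based cores are dilated isotropically via an exact
  Euclidean distance transform. Boundary points are assigned to the inner
  region (deterministic tie-break).
- Circularity: C = 4πA/P², with the perimeter taken from the 0.5-level
  boundary polygon through pixel-edge midpoints (45° corner cutting via
  `contourLines`), longest (outer) contour; holes ignored, matching a
  wand-style selection. A rasterized disk of radius 50 px scores ≈ 0.89; a
  1×200 px bar ≈ 0.0156. A single-pixel component is defined through its
  unit square (C = 4π/16) and flagged. Exact parity with any particular
  GUI's perimeter estimator is not guaranteed; the estimator is documented
  and tested on reference shapes.
- Phenotype classes: filamentous ≤ 0.14 < intermediate ≤ 0.28 < compact.
  The published class ranges leave a 0.141–0.149 gap, resolved by
  thresholding exactly at 0.14 and 0.28.
- Log-normality of plaque areas: an omnibus normality test on log(areas).
  The environment provides no D'Agostino–Pearson implementation, so the
  Anderson–Darling omnibus test (`nortest::ad.test`) is delegated to; at
  the sample sizes involved both tests have comparable power against the
  alternatives of interest.
- The spherical volume-ratio helper reports the exact cube ratio
  (R_tot/r_core)³ and does not target any rounded published figure.

## Matrix metrics

Isodata (Ridler–Calvard intermeans) thresholding; percent area per ROI;
Zhang–Suen thinning (a 5-px bar loses up to ~half its width per end — an
inherent property of the thinning scheme); box-counting fractal dimension
over dyadic box sizes 2…side/4 anchored at the origin, −slope of
log N(s) vs log s; an empty mask scores 0 by convention (the regime inside
amyloid cores). Whether the fractal dimension is computed on the skeleton
or the raw mask is not specified upstream; the default is the skeleton
(skeletonization precedes the analysis in the reference workflow), with
`fractal_on = "mask"` available, and the choice recorded in outputs.
Dyadic box grids are incommensurate with triadic test sets: a depth-4
Sierpinski raster (81 px) underestimates (≈1.74), while a depth-5 raster
(243 px) gives ≈1.85 vs log8/log3 ≈ 1.893 — oracle tests use the 243-px
raster.

## The simulator and what passing tests mean

`simkit` draws log-normal core areas (ex-vivo median 134.2 µm² by
default), Euler–Maruyama Brownian steps with per-axis SD √(2DΔt),
reflecting boundaries (radial reflection; exact triangle-wave folding for
channels), 10× substepping inside confinement domains so reflection stays
accurate near boundaries, region labels fixed at birth (particles reflect
at region boundaries, keeping ground-truth labels unambiguous), immobile
subpopulations with D = 0, and integrated-Gaussian PSF rendering
(default camera: 160 nm pixels, 130 nm PSF σ — Nyquist-sampled; the
upstream pixel size is unstated, so these are configurable defaults) with
Poisson noise into 16-bit frames. QD density per field and photon budgets
are likewise unstated upstream; the defaults (20 particles per 30×30 µm
FOV, 2000–5000 photons/frame) are package choices documented here, not
inferred values.

Problem sizes in the shipped tests and acceptance script are desk-scale
choices: 500 trajectories × 60 frames for diffusion recovery, 300 × 84
for confinement, 200 × 100 for widths, 20 000 points for penetrability.

The generator emulates region-dependent diffusivity, confinement,
immobile fractions, localization noise, and plaque/matrix mask
morphologies. It does **not** emulate photophysics (blinking, bleaching),
axial (3D) motion and defocus, anisotropic or hop diffusion, curved ECS
channels, vessel shadows, or spatially varying background. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated motion and noise models — not robustness to every artefact of
live-tissue imaging.

## Reproducibility

Every stochastic stage consumes the caller's seed; the pipeline sets one
top-level seed and the acceptance script derives independent sub-seeds per
quantity. `run_pipeline()` writes a manifest (config snapshot with
defaulted keys marked, package version, seed, input checksums, per-stage
record counts, warnings); identical configs and inputs reproduce outputs
bit-identically.
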