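# ecsrheomap

Quantitative rheology of the brain **extracellular space (ECS)** in and
around amyloid plaques, from single-particle tracking (SPT) data — an R
package for researchers analysing quantum-dot (QD) or single-walled
carbon-nanotube (SWCNT) tracking movies of brain tissue, together with a
synthetic-data generator that makes every stage testable with known ground
truth.

## What it computes

**MSD rheology.** For each linked trajectory the time-averaged mean squared
displacement is

MSD(τ) = ⟨ |r(t+τ) − r(t)|² ⟩ₜ ,

from which the package derives

- the **instantaneous diffusion coefficient** D_inst = slope/4 of an OLS
  line (free intercept) through the first 4 MSD points;
- the **confinement area**, the mean MSD over the plateau window
  0.6–0.8 s — for a particle confined in a reflecting disk of radius R this
  plateau equals E|P₁−P₂|² = R² for uniform P₁, P₂, so it measures the area
  explored;
- the **mobile/immobile split** at the strict threshold
  D_inst < 0.005 µm²/s, with the field-of-view inclusion rule for immobile
  fractions;
- the paired **relative change** 100·(x−y)/(0.5·(x+y)) between adjacent
  compartments.

**Plaque geometry.** Concentric Amyloid / Ring / Out ROIs built from the
core's equivalent radius r = √(A/π) with ring width 1.82·r; localization
densities and **penetrability ratios** (outer/inner density, ≈1 for free
exchange); morphometry and **circularity phenotyping**
C = 4πA/P² (filamentous ≤ 0.14 < intermediate ≤ 0.28 < compact).

**Nanotube local maps.** Sliding 10-frame windows with 3-point MSD fits
give local D_inst along a trajectory; 6-point covariance-eccentricity
windows locate maximal confinement, where the **local ECS width** is
estimated as w = √(12·max(σ²_minor − Δx², 0)) under a uniform
transverse-occupancy model (Δx = 30 nm localization precision; one-time
simulation calibration). The error model ΔD_inst = Δx²/t gives
0.01 µm²/s at Δx = 30 nm and t = 3 × 30 ms.

**Matrix metrics.** Isodata thresholding, percent signal area per ROI,
Zhang–Suen skeletonization, and box-counting fractal dimension.

**Simulation kit.** Log-normal plaque geometries, reflecting-boundary
Brownian motion (free, disk-confined, channel-confined), PSF-rendered
16-bit movies with Poisson noise, plaque masks of controlled circularity,
and reticular/degraded/empty matrix masks.

## Worked example

Simulate QDs confined in a 0.305 µm reflecting disk, observed at 28 Hz
with 30 nm localization noise, and recover diffusion and confinement:

```r
library(ecsrheomap)
set.seed(1)

tr <- simulate_confined_trajectories(n = 300, D = 0.15, radius = 0.305,
                                     n_frames = 84, frame_interval = 1/28,
                                     substeps = 10)
tr   <- add_observation_jitter(tr, 0.030)
recs <- analyze_trajectories(tr, frame_interval = 1/28)

median(recs$confinement_um2, na.rm = TRUE)
#> [1] 0.09256615          # analytic plateau R^2 = 0.0930 um^2
mean(recs$mobile)
#> [1] 1                   # all trajectories above 0.005 um^2/s
dinst_error(0.030, 3, 0.030)
#> [1] 0.01                # D error from 30 nm noise over a 3x30 ms fit
```

The recovered median confinement area (0.0926 µm²) sits within 1% of the
analytic disk plateau R² = 0.0930 µm²; `dinst_error()` is the closed-form
localization-noise floor on instantaneous diffusion estimates.

An end-to-end run (simulate → per-ROI rheology) via the pipeline:

```r
cfg <- validate_config(list(mode = "simulate", seed = 7, field_px = 256,
                            n_per_region = 10))
run_pipeline(cfg, "out")          # ground truth, trajectories, ROI, manifest
cfg2 <- validate_config(list(mode = "qd", input = "out/trajectories.csv",
                             roi = "out/roi.json"))
run_pipeline(cfg2, "out")         # rheology.csv, summary.csv, msd_ensemble.csv
```

A thin command-line wrapper lives at `inst/cli/ecs-rheomap.R`.

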