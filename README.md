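# nucdetect

Accurate detection, segmentation and tracking of fluorescently labeled
cell nuclei that are packed too densely for conventional blob detection —
the situation in whole-brain activity imaging of the *C. elegans* head,
where ~200 neuronal nuclei sit at nearest-neighbour distances of
4.30 ± 2.13 µm (often under two nucleus diameters) with peak brightness
spanning an order of magnitude. Classic local-peak + watershed detection
silently fuses a dim nucleus into a bright neighbour; for activity
imaging every such false negative is a lost neuron.

## Method

Each nucleus is modeled as an unnormalized trivariate Gaussian
*f<sub>k</sub>(x) = π<sub>k</sub> exp(−½ (x−μ<sub>k</sub>)ᵀ
Σ<sub>k</sub>⁻¹ (x−μ<sub>k</sub>))* — peak intensity π<sub>k</sub>,
centre μ<sub>k</sub> (µm), covariance Σ<sub>k</sub> (µm²) whose eigenvalue
square roots are the nucleus half-radii. The pipeline:

1. **Preprocess** — subpixel phase-correlation registration, 3D median
   denoising, rolling-ball style background subtraction, Gaussian blur.
2. **Blob detection** — global (triangle/Otsu) threshold, ellipsoidal
   local-maximum seeds, 3D seeded grayscale watershed, small-region
   removal.
3. **Clump splitting** — per-voxel principal curvatures of the
   iso-intensity surfaces (eigenvalues of the level-set shape operator,
   computed in physical µm units); the smaller curvature is positive
   everywhere inside a single Gaussian blob but negative in the waist
   between two, so regions with enough qualifying negative-curvature
   voxels are flagged, the negative voxels removed, and the remainder
   re-segmented by a distance-transform watershed.
4. **Least-squares Gaussian-mixture fit** — alternate optimization (exact
   joint linear solve for all peaks; per-component Levenberg–Marquardt
   for centres and covariances with analytic Jacobians); over-segmented
   duplicates merged by a centre-distance rule. Warm-start **tracking**
   propagates the fitted mixture through time-lapse recordings with
   nucleus sizes frozen, extracting per-channel intensity traces.

A first-class synthetic-scene generator reproduces the measured packing
statistics (spacing, half-radii, intensity spread, noise), so every stage
is testable without microscope data, and detection quality is scored by
mutual-nearest-neighbour matching (TP/FP/FN rates, F-measure, accuracy).

## Worked example

```r
library(nucdetect)

# a 60-nucleus scene with the measured packing statistics + mild noise
truth  <- sample_scene(scene_spec(n_nuclei = 60,
                                  volume_extent = c(30, 24, 16), seed = 1))
volume <- render_volume(truth, seed = 1)

det <- run_detect(volume, verbose = TRUE)
#> threshold 10.58 keeps 21.5% of voxels
#> 43 local peaks
#> 43 regions after cleaning
#> 26 regions flagged as under-segmented, 19 regions added
#> 58 components after fitting (merged)

run_eval(det$mixture, truth)$indices
#> $tp_rate   [1] 0.9333
#> $fp_rate   [1] 0.0333
#> $fn_rate   [1] 0.0667
#> $f_measure [1] 0.9492
#> $accuracy  [1] 0.9032
```

Of 60 nuclei, only 43 have a local intensity peak of their own — the
other 17 are dim cells whose peaks are swamped by bright neighbours.
Curvature splitting recovers most of them (26 fused regions flagged, 19
extra regions created); the mixture fit localizes each survivor to
subvoxel accuracy. The residual misses are contact pairs closer than
about two Gaussian widths, where no negative-curvature evidence exists at
all (see the methods vignette).

A command-line interface with `simulate`, `detect`, `track` and `eval`
subcommands ships in `inst/scripts/nucdetect.R`.

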