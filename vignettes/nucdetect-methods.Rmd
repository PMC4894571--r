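---
title: "Detecting densely packed nuclei in 3D: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting densely packed nuclei in 3D: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In whole-brain calcium imaging of adult *C. elegans*, roughly 200 neuronal
nuclei crowd into the head ganglia. Their fluorescence profiles are
approximately Gaussian: brightness rises smoothly toward each nucleus
centre, with a typical per-axis half-radius (the distance at which the
profile falls to exp(-1/2) of its peak) of about 1.10 µm. Nearest-neighbour
centre distances average 4.30 ± 2.13 µm — often less than two nucleus
diameters — and peak brightness varies by an order of magnitude between
cells. Under these conditions classic blob detection (local peaks + seeded
watershed) fails in a characteristic way: a dim nucleus adjacent to a
bright one has no local intensity maximum of its own, because the bright
tail swamps its peak. The dim cell is silently fused into its neighbour's
region and is lost. For activity imaging, where every neuron's trace
matters, such false negatives are the dominant error.

## The model

Each nucleus k is modeled as an *unnormalized* trivariate Gaussian

$$ f_k(x) \;=\; \pi_k \exp\!\left(-\tfrac12 (x-\mu_k)^\top
   \Sigma_k^{-1}(x-\mu_k)\right), $$

with peak intensity $\pi_k$ (arbitrary fluorescence units), centre $\mu_k$
(µm) and covariance $\Sigma_k$ (µm²), whose eigenvalue square roots are the
per-axis half-radii. The image is modeled as $\sum_k f_k(x)$ plus
background and noise; the package both *generates* volumes from this model
(`sample_scene()`, `render_volume()`) and *fits* it to volumes
(`fit_mixture()`).

## The pipeline

`run_detect()` chains four stages.

**1. Preprocessing** (`preprocess_volume()`): a 3D median filter (box of
(2r+1)³ voxels, default r = 1) removes salt-and-pepper and shot-like
outliers; a per-plane rolling-ball style background estimate (gray-scale
box opening, default half-width 50 voxels) is subtracted and negatives
clamped to zero; a separable Gaussian blur regularizes the image for
finite-difference curvature. In-plane translation between planes or frames
is corrected beforehand by subpixel phase correlation
(`register_translation()`), with the middle plane as the within-stack
reference and chained references across time so drift does not accumulate.

The blur default is 1 voxel per axis. Heavier smoothing (2 voxels) was
measured to *hurt* detection on packed scenes: close pairs sit at 1.5–2.2
µm, about two Gaussian widths, and extra blur erases exactly the
inter-nucleus saddle that the curvature stage needs. The median filter
already removes the impulse noise that the blur would otherwise have to
handle.

**2. Blob detection** (`detect_peaks()`, `seeded_watershed()`,
`clean_regions()`): obvious background is removed by a global threshold.
The default method is the triangle (Rosin) threshold rather than Otsu:
with a tenfold spread in nucleus brightness the volume histogram is a
dominant background mode with a long bright tail, and Otsu tends to cut
*between* the dim and bright nuclei, deleting the dim ones wholesale,
while the triangle rule cuts just above the background mode. Local maxima
within an ellipsoidal neighbourhood (default radius 3 voxels; intensity
ties broken toward the lexicographically smallest coordinate, so tied
plateaus yield one seed) seed a 3D grayscale watershed that floods the
full mask. Regions smaller than `min_voxels` (default 27, a 3³ core — far
below any real nucleus at 0.24 µm sampling) are removed. A per-region
automatic threshold is available (`region_threshold = "otsu"` or
`"triangle"`) but the pipeline default is `"none"`: the global threshold
has already removed background, and a second cut inside a region
containing a bright and a dim nucleus can remove the saddle voxels between
them — precisely the evidence the next stage needs.

**3. Curvature-driven clump splitting** (`principal_curvatures()`,
`negative_mask()`, `split_undersegmented()`): at every voxel the two
principal curvatures of the iso-intensity surface through that voxel are
computed in closed form from the image gradient g and Hessian H (central
finite differences scaled by the per-axis voxel size, so curvatures are in
1/µm and anisotropic sampling is handled):

$$ \kappa_{mean} = \frac{g^\top H g - |g|^2\,\mathrm{tr}H}{2|g|^3},
   \qquad
   \kappa_{gauss} = \frac{g^\top H^{*} g}{|g|^4}, $$

with $H^{*}$ the adjugate of H, and
$\kappa_{\min,\max} = \kappa_{mean} \mp \sqrt{\kappa_{mean}^2 -
\kappa_{gauss}}$. The sign convention makes both curvatures positive
everywhere inside a single Gaussian blob; wherever two blobs overlap, the
iso-surfaces develop a waist and the smaller curvature turns negative.
Voxels with gradient magnitude below `grad_epsilon` (default 10⁻³ of the
volume maximum per µm — blob centres and flat background) and the
one-voxel volume border (replicate padding) make no curvature claim.

A region is flagged as under-segmented when its count of *qualifying*
negative voxels strictly exceeds `count_threshold` (default 10): a
negative voxel qualifies only if its connected negative component reaches
the region border (interior islands are noise) and the voxel itself lies
deeper than `border_margin` (default 1 voxel) from the border (voxels
hugging the border belong to a correct segmentation). Flagged regions are
split: the negative voxels are removed, the remainder is Euclidean
distance-transformed in physical µm (exact separable transform, verified
against brute force), distance maxima seed a second watershed on the
negated distance landscape, and the removed voxels are finally handed to
the geodesically nearest product so the region's voxel set is conserved.

Three guards keep the re-seeding honest, each added after watching a
naive version fail in a specific way. Maxima within `seed_merge_um`
(default 1.0 µm, below the 1.5 µm packing floor so genuinely distinct
nuclei always keep their own seeds) of a higher maximum are suppressed,
and *exactly tied* maxima — a quantization artifact of the distance
transform, never two different nuclei — are suppressed out to twice that
radius with a lexicographic tie-break. A seed must be at least
`seed_min_depth_um` (0.2 µm, just under one voxel) deep; a dim nucleus
squeezed between the curvature sheet and the region border can be as
little as one voxel deep, so this floor only rejects empty maxima.
Finally, after the watershed a product whose inscribed depth rises less
than `prominence_um` (default 0.05 µm) above the saddle to a deeper
neighbour is absorbed into it. The prominence default is deliberately a
fraction of a voxel: ripples along a plate-shaped remainder have
sub-voxel prominence while genuine nucleus cores rise far above their
saddles; larger values (tried at 0.3 µm) measurably suppress genuine
splits of dim nuclei.

The method has a hard geometric limit, shared with the approach it
implements: two Gaussians closer than about two widths (≈ 2.2 µm at these
nucleus sizes) produce *no* negative-curvature region at all — the fused
blob is convex in the iso-surface sense everywhere. Contact pairs at the
1.5 µm packing floor are therefore intrinsically unsplittable, and this —
not algorithmic failure — sets the ceiling on recall in maximally packed
scenes.

**4. Least-squares Gaussian-mixture fitting** (`initialize_mixture()`,
`fit_mixture()`, `merge_close_components()`): one component per
post-split region, centre initialized at the intensity-weighted centroid,
covariance at the isotropic typical half-radius (1.10 µm), peak at the
region maximum. The fit minimizes the residual sum of squares by alternate
optimization: (a) with shapes held, all peaks $\pi_k$ solve one joint
linear least-squares problem exactly (sparse normal equations; negative
solutions removed by one-at-a-time active-set elimination); (b) each
component's centre and covariance is refined by Levenberg–Marquardt on its
own residual window with the others frozen, the covariance parameterized
through its Cholesky factor (log-diagonal) so it stays positive definite,
with an analytic Jacobian. Every step is accepted only if the SSE does not
increase, so the SSE trace is monotone nonincreasing by construction.
Covariance eigenvalue square roots are clamped to [0.3, 3] µm to prevent
collapse onto specks or explosion across neighbours.

Components are evaluated on windows of `support_radius` = 4 standard
deviations (SSE differs from full evaluation by well under 0.1%);
refinement uses 3σ windows, where all localization information lives.
After convergence, while any two centres are closer than `merge_cutoff`
the dimmer of the closest pair is removed and the mixture refit.
`merge_cutoff` defaults to 1.4 µm, just *below* the 1.5 µm packing floor:
distinct nuclei can never be that close, so only duplicate fits of one
nucleus are ever merged, and no legitimate close pair is deleted. (An
earlier default of 2.0 µm — "twice the half-radius" — was found to delete
correctly detected pairs at 1.5–2.0 µm separation.)

Intensities in other channels are obtained by the same joint linear solve
with all shapes frozen (`estimate_channel_scalings()`), clamped at zero.

**Tracking** (`track_series()`): the converged mixture of frame t warm-
starts frame t+1. Peaks and centres refit; covariances are fully frozen by
default (a `freeze = "rotation"` option frees orientation while keeping
the eigenvalues — the nucleus sizes — fixed). Whole-animal in-plane
translation is pre-corrected per frame by phase correlation of the maximum
projections. Component count and order are fixed for the run, so identity
is conserved by construction; a component whose centre jumps more than
`max_step_um` (3 µm) or leaves the volume is reset to its previous state
and flagged rather than aborting the run. Per-channel intensities are
re-estimated at every frame, which is what ratiometric activity traces
(`ratio_trace()`) need.

**Evaluation** (`match_points()`, `compute_indices()`): detected centres
(the fitted $\mu_k$) are matched to ground truth by mutual nearest
neighbours — a pair counts as a true positive only if each point is the
other's closest counterpart, with distance ties broken toward the lowest
index for determinism, and no distance ceiling by default. From TP/FP/FN
(GT = TP + FN): the TP/FP/FN rates (each over GT), F-measure
2TP/(2TP+FN+FP) and accuracy TP/(TP+FN+FP). Non-integer counts are
accepted so that across-animal mean counts can run through the same
arithmetic.

## The synthetic scene generator

`scene_spec()` / `sample_scene()` / `render_volume()` emulate the measured
structure of the real data: ellipsoidal nuclei with per-axis half-radii
drawn around 1.10 µm (sd 0.15 µm, giving max/min axis ratios near the
observed ~1.3), peak intensities log-uniform over one decade, and a
nearest-neighbour distance distribution targeted at 4.30 ± 2.13 µm with a
hard 1.5 µm separation floor. Placement is sequential: each nucleus draws
its target nearest-neighbour distance, then searches for a position
exactly that far from an existing nucleus with everything else at least as
far away; anchors are preferred among nuclei whose own current
nearest-neighbour distance is close to the drawn value, which keeps the
scene-wide mean on target (naive chain placement collapses the mean to
about half the target). The default 52 × 40 × 24 µm extent reaches the
observed packing density at 200 nuclei; the default voxel size
(0.240, 0.240, 0.252) µm matches confocal sampling with slight axial
anisotropy, so anisotropy handling is always exercised. Noise is applied
after the signal: constant background plus a linear gradient along x1,
additive Gaussian noise, then salt-and-pepper replacement — the
components that Step 1's median filter and background subtraction are
there to remove.

What the generator does *not* emulate: optics (no PSF convolution),
photobleaching, intensity deviations from Gaussian profile shape, and
nonrigid body deformation (time series drift rigidly). Passing tests on
these scenes therefore demonstrates the pipeline's behaviour under its own
model assumptions — the regime the method is designed for — not robustness
to every artifact of real microscopy.

## Numerical choices and degenerate inputs

* Curvature uses plain 3-point central differences with no extra
  smoothing; Step 1's blur is the regularizer.
* Single-plane volumes run the same pipeline with the level-*curve*
  curvature (one principal curvature) substituted in 2D, and the third
  covariance axis held fixed during fitting.
* A constant volume is rejected by the automatic thresholds; a fixed
  threshold above the maximum yields an empty mask with a warning.
* A region entirely covered by negative curvature is returned unsplit
  with a warning.
* Watershed ties (equal intensity) are processed in insertion order;
  peak-detection ties go to the lexicographically smallest coordinate —
  all outputs are bit-reproducible for a fixed configuration and seed.
* The registration estimator refines the integer phase-correlation peak
  with a locally upsampled DFT; with upsampling 20 the error stays below
  0.1 voxel on blurred test images.

## Problem sizes used in the test suite

The bundled tests run entirely on generated data: the canonical
bright/dim doublet (π 120 vs 40 at 3 µm spacing) on a 61×41×41 grid,
20–60-nucleus scenes for fitting and detection, a 200-nucleus scene at
the full measured packing density (217×167×96 voxels) for the end-to-end
recall check, and a 10-frame, 5-nucleus drift series for tracking. These
sizes keep the whole suite within ordinary desktop patience while leaving
every stage's behaviour measurable.

## Known limitations

* Pairs below ~2σ separation cannot be split (no negative-curvature
  signal exists); they are the residual false negatives in packed scenes.
* Splitting is single-pass (no recursive re-splitting of products).
* Component count is fixed during tracking: appearance, disappearance,
  division and death are out of scope.
* The per-region threshold method of the original description is not
  identifiable from the text; Otsu and triangle are provided,
  with the pipeline defaulting to no per-region cut.
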