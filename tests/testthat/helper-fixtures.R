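# Shared fixtures, built lazily and memoized for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The canonical bright/dim nucleus pair: pi 120 at (-1,0,0) with per-axis
# half-radii (1.10, 0.89, 1.35), pi 40 at (2,0,0) with radii scaled by 0.9.
doublet_components <- function() {
  list(gaussian_component(120, c(-1, 0, 0), diag(c(1.10, 0.89, 1.35)^2)),
       gaussian_component(40, c(2, 0, 0),
                          diag((c(1.10, 0.89, 1.35) * 0.9)^2)))
}

doublet_truth <- function() {
  structure(list(components = doublet_components(),
                 spec = list(noise = NULL)),
            class = "ground_truth")
}

doublet_volume <- function() {
  fixture("doublet_volume", function() {
    render_volume(doublet_truth(), voxel_size = c(0.2, 0.2, 0.2),
                  noise = NULL, extent = c(12, 8, 8),
                  origin = c(-6, -4, -4))
  })
}

# Single isotropic Gaussian blob on a fine grid (the sphere oracle carrier).
isotropic_blob <- function() {
  fixture("isotropic_blob", function() {
    tr <- structure(
      list(components = list(gaussian_component(100, c(5, 5, 5),
                                                diag(1, 3))),
           spec = list(noise = NULL)),
      class = "ground_truth")
    render_volume(tr, voxel_size = c(0.1, 0.1, 0.1), noise = NULL,
                  extent = c(10, 10, 10))
  })
}

# Independent direct evaluation of a Gaussian mixture at one physical point
# (the rendering oracle; deliberately scalar and loop-based).
mixture_value_at <- function(components, x) {
  total <- 0
  for (cc in components) {
    d <- x - cc$mu
    total <- total + cc$pi * exp(-0.5 * (stats::mahalanobis(
      matrix(x, 1), center = cc$mu, cov = cc$sigma)))
  }
  total
}

# Radius array (um) of a volume's voxels from a centre point.
radius_array <- function(v, center) {
  ax <- voxel_axes(v)
  d <- dim(v$data)
  r <- array(0, d)
  for (k in seq_len(d[3]))
    for (j in seq_len(d[2]))
      r[, j, k] <- sqrt((ax[[1]] - center[1])^2 + (ax[[2]][j] - center[2])^2 +
                          (ax[[3]][k] - center[3])^2)
  r
}

# Small multi-nucleus scene shared across gmm/tracker tests.
scene20 <- function() {
  fixture("scene20", function() {
    sp <- scene_spec(n_nuclei = 20, volume_extent = c(24, 20, 14),
                     min_separation = 3, spacing_mean = 4.3,
                     spacing_sd = 1.5, noise = NULL, seed = 42)
    tr <- sample_scene(sp)
    list(truth = tr, volume = render_volume(tr, noise = NULL, seed = 42))
  })
}

# Config that skips preprocessing (for noiseless analytic volumes).
raw_config <- function(...) {
  pipeline_config(preprocess = list(median_radius = 0,
                                    background_radius = 0,
                                    blur_sigma = c(0, 0, 0)), ...)
}

# A small tracked scene: 5 well-separated nuclei drifting rigidly.
track_fixture <- function() {
  fixture("track_fixture", function() {
    sp <- scene_spec(n_nuclei = 5, volume_extent = c(18, 14, 10),
                     spacing_mean = 5, spacing_sd = 1, min_separation = 3.5,
                     noise = NULL, seed = 17)
    tr <- sample_scene(sp)
    series <- render_series(tr, n_frames = 10,
                            drift_per_frame = c(0.25, 0.1, 0.05),
                            noise = NULL, seed = 17)
    fit0 <- fit_mixture(series$frames[[1]], mixture_model(tr$components),
                        fit_options(max_iter = 3))
    list(truth = tr, series = series, fit0 = fit0)
  })
}

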