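#' Specification of a synthetic nucleus scene
#'
#' Describes a field of roughly ellipsoidal nuclei whose fluorescence
#' profiles are unnormalized trivariate Gaussians, packed with the density
#' statistics observed for C. elegans head neurons: nearest-neighbour centre
#' spacing 4.30 +/- 2.13 um, typical per-axis half-radius about 1.10 um, and
#' peak intensities spanning one order of magnitude. The defaults reproduce
#' those study conditions; the volume extent is chosen so that a 200-nucleus
#' scene reaches the observed packing density.
#'
#' @param n_nuclei number of nuclei (>= 0).
#' @param volume_extent physical size of the imaged volume, um (length 3).
#' @param spacing_mean,spacing_sd target nearest-neighbour centre distance
#'   distribution, um.
#' @param half_radius_mean,half_radius_sd per-axis half-radius (the Gaussian
#'   standard deviation along that axis), um.
#' @param intensity_decades log10 range of the peak intensities pi_k; peaks
#'   are drawn log-uniformly over \code{[pi_max / 10^decades, pi_max]}.
#' @param pi_max brightest peak intensity (arbitrary units).
#' @param min_separation minimum allowed centre-to-centre distance, um
#'   (nuclei never fully overlap).
#' @param noise list with \code{salt_pepper_fraction} (probability),
#'   \code{gaussian_sd}, \code{background_level} (intensity units) and
#'   \code{background_gradient} (intensity units per um along x1).
#' @param seed integer seed; the whole scene is deterministic given it.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(n_nuclei = 200,
                       volume_extent = c(52, 40, 24),
                       spacing_mean = 4.30, spacing_sd = 2.13,
                       half_radius_mean = 1.10, half_radius_sd = 0.15,
                       intensity_decades = 1, pi_max = 200,
                       min_separation = 1.5,
                       noise = list(salt_pepper_fraction = 1e-3,
                                    gaussian_sd = 1.0,
                                    background_level = 2.0,
                                    background_gradient = 0.05),
                       seed = 1L) {
  stopifnot(n_nuclei >= 0, length(volume_extent) == 3,
            all(volume_extent > 0), spacing_mean > 0, spacing_sd >= 0,
            half_radius_mean > 0, intensity_decades >= 0, pi_max > 0,
            min_separation >= 0)
  structure(list(n_nuclei = as.integer(n_nuclei),
                 volume_extent = as.numeric(volume_extent),
                 spacing_mean = spacing_mean, spacing_sd = spacing_sd,
                 half_radius_mean = half_radius_mean,
                 half_radius_sd = half_radius_sd,
                 intensity_decades = intensity_decades, pi_max = pi_max,
                 min_separation = min_separation,
                 noise = noise, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Sample nucleus positions, shapes and intensities for a scene
#'
#' Centres are placed sequentially. Each new nucleus draws its target
#' nearest-neighbour distance d from the spacing distribution (truncated at
#' \code{min_separation}), then searches for a position exactly d away from
#' an existing nucleus with every other centre at least d away, so that d is
#' the realized nearest-neighbour distance of the new point. Anchors are
#' preferred among nuclei whose own current nearest-neighbour distance is
#' close to d, which keeps the scene-wide distribution centred on the
#' target; if no position fits, d is gradually shrunk, and the packing is
#' declared infeasible when the search budget runs out. Per-axis half-radii
#' are drawn around \code{half_radius_mean} and become the square roots of
#' the (diagonal) covariance eigenvalues; peak intensities are log-uniform
#' over the requested number of decades.
#'
#' @param spec a [scene_spec()].
#' @param max_tries placement-search budget per nucleus before the packing
#'   is declared infeasible.
#' @return An object of class \code{ground_truth}: list with
#'   \code{components} (list of [gaussian_component()]) and \code{spec}.
#' @export
sample_scene <- function(spec, max_tries = 800) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- spec$n_nuclei
  ext <- spec$volume_extent
  margin <- min(spec$half_radius_mean, ext / 2.001)
  lo <- pmin(margin, ext / 2)
  hi <- pmax(ext - margin, ext / 2)
  centers <- matrix(numeric(0), ncol = 3)
  if (n > 0) {
    centers <- matrix(0, n, 3)
    cur_nn <- rep(Inf, n)
    centers[1, ] <- lo + stats::runif(3) * (hi - lo)
    if (n > 1) {
      for (i in 2:n) {
        repeat {
          d <- stats::rnorm(1, spec$spacing_mean, spec$spacing_sd)
          if (d >= spec$min_separation) break
        }
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          if (t %% 100L == 0L)  # shrink the target if it will not fit
            d <- max(d * 0.9, spec$min_separation)
          sc <- abs(cur_nn[seq_len(i - 1L)] - d)
          pool <- order(sc)[seq_len(min(8L, i - 1L))]
          anchor <- centers[pool[sample.int(length(pool), 1L)], ]
          u <- stats::rnorm(3)
          cand <- anchor + d * u / sqrt(sum(u^2))
          if (any(cand < lo) || any(cand > hi)) next
          dv <- sqrt(rowSums(sweep(centers[seq_len(i - 1L), ,
                                           drop = FALSE], 2, cand)^2))
          # the anchor (at distance d) must be the nearest neighbour
          if (min(dv) < d - 1e-9) next
          centers[i, ] <- cand
          cur_nn[i] <- d
          cur_nn[seq_len(i - 1L)] <- pmin(cur_nn[seq_len(i - 1L)], dv)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("infeasible packing: could not place nucleus ", i, " of ", n,
               " after ", max_tries, " tries")
      }
    }
  }
  comps <- vector("list", n)
  for (i in seq_len(n)) {
    hr <- abs(stats::rnorm(3, spec$half_radius_mean, spec$half_radius_sd))
    hr <- pmax(hr, 0.4 * spec$half_radius_mean)
    pk <- spec$pi_max * 10^(-stats::runif(1, 0, spec$intensity_decades))
    comps[[i]] <- gaussian_component(pi = pk, mu = centers[i, ],
                                     sigma = diag(hr^2, 3))
  }
  structure(list(components = comps, spec = spec), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei in (%.3g x %.3g x %.3g) um\n",
              length(x$components), x$spec$volume_extent[1],
              x$spec$volume_extent[2], x$spec$volume_extent[3]))
  invisible(x)
}

#' Centres of a ground truth or mixture as a matrix
#' @param x a \code{ground_truth} or \code{mixture_model}.
#' @return Numeric matrix, one row per component, columns x1..x3 (um).
#' @export
component_centers <- function(x) {
  comps <- x$components
  if (!length(comps)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, lapply(comps, function(cc) cc$mu))
}

#' Peak intensities of a ground truth or mixture
#' @param x a \code{ground_truth} or \code{mixture_model}.
#' @return Numeric vector of pi_k values.
#' @export
component_intensities <- function(x)
  vapply(x$components, function(cc) cc$pi, numeric(1))

default_voxel_size <- function() c(0.240, 0.240, 0.252)

#' Render a noiseless or noisy volume from ground truth
#'
#' The signal at voxel position x is the Gaussian mixture
#' \code{sum_k pi_k exp(-t(x - mu_k) Sigma_k^-1 (x - mu_k) / 2)}, evaluated
#' exactly on the voxel grid (components are cut off beyond 8 standard
#' deviations, below double precision relative to the peak). Noise is applied
#' after the signal, in the order: constant background plus linear gradient
#' along x1, additive Gaussian noise, then salt-and-pepper replacement
#' (half of affected voxels set to 0, half to twice the maximum signal).
#'
#' @param truth a \code{ground_truth} (possibly with zero components).
#' @param voxel_size voxel edge lengths, um. Default matches a confocal
#'   stack with slightly anisotropic sampling, (0.240, 0.240, 0.252).
#' @param noise noise record; defaults to the spec embedded in \code{truth};
#'   pass \code{NULL} for a noiseless render.
#' @param seed seed for the noise draws (signal itself is deterministic).
#' @param extent physical extent, um; defaults to the scene extent.
#' @param origin position of the first voxel centre, um.
#' @return A \code{volume_image}.
#' @export
render_volume <- function(truth, voxel_size = default_voxel_size(),
                          noise = truth$spec$noise, seed = 1L,
                          extent = truth$spec$volume_extent,
                          origin = c(0, 0, 0)) {
  stopifnot(all(voxel_size > 0))
  dims <- pmax(floor(extent / voxel_size + 1e-9), 1) + 1
  axes <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) *
                   voxel_size[a])
  arr <- array(0, dim = dims)
  for (cc in truth$components)
    arr <- add_component_signal(arr, axes, cc, support_radius = 8)
  if (!is.null(noise)) {
    set.seed(seed)
    bg <- noise$background_level
    if (is.null(bg)) bg <- 0
    grad <- noise$background_gradient
    if (is.null(grad)) grad <- 0
    if (bg != 0 || grad != 0)
      arr <- arr + bg + grad * (axes[[1]] - axes[[1]][1])  # recycled along x1
    gs <- noise$gaussian_sd
    if (!is.null(gs) && gs > 0)
      arr <- arr + stats::rnorm(length(arr), 0, gs)
    sp <- noise$salt_pepper_fraction
    if (!is.null(sp) && sp > 0) {
      nhit <- stats::rbinom(1, length(arr), sp)
      if (nhit > 0) {
        idx <- sample.int(length(arr), nhit)
        salt <- stats::runif(nhit) < 0.5
        arr[idx[salt]] <- 2 * max(arr)
        arr[idx[!salt]] <- 0
      }
    }
  }
  volume_image(arr, voxel_size, origin = origin)
}

# Add one unnormalized Gaussian to an array over its local support window.
add_component_signal <- function(arr, axes, comp, support_radius = 8) {
  dims <- dim(arr)
  sd_ax <- sqrt(diag(comp$sigma))
  rng <- lapply(1:3, function(a) {
    which(axes[[a]] >= comp$mu[a] - support_radius * sd_ax[a] &
          axes[[a]] <= comp$mu[a] + support_radius * sd_ax[a])
  })
  if (any(vapply(rng, length, integer(1)) == 0)) return(arr)
  g <- eval_gaussian_grid(comp, axes[[1]][rng[[1]]], axes[[2]][rng[[2]]],
                          axes[[3]][rng[[3]]])
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + g
  arr
}

# Evaluate pi * exp(-0.5 (x-mu)' Sigma^-1 (x-mu)) on the grid x1 x x2 x x3.
eval_gaussian_grid <- function(comp, x1, x2, x3) {
  n1 <- length(x1); n2 <- length(x2); n3 <- length(x3)
  pts <- cbind(rep(x1 - comp$mu[1], times = n2 * n3),
               rep(rep(x2 - comp$mu[2], each = n1), times = n3),
               rep(x3 - comp$mu[3], each = n1 * n2))
  si <- solve(comp$sigma)
  q <- rowSums((pts %*% si) * pts)
  array(comp$pi * exp(-0.5 * q), dim = c(n1, n2, n3))
}

#' Render a drifting time series
#'
#' Frame t renders the ground truth with every centre displaced by
#' \code{(t - 1) * drift_per_frame} (rigid whole-animal drift). The per-frame
#' displaced truths are returned alongside the images.
#'
#' @param truth a \code{ground_truth}.
#' @param n_frames number of frames (>= 1).
#' @param drift_per_frame rigid displacement per frame, um (length 3).
#' @param voxel_size,noise,seed,extent,origin as in [render_volume()]; each
#'   frame uses seed \code{seed + t - 1} for its noise draws.
#' @param pi_series optional function \code{(t, pi0)} returning the vector of
#'   per-component peak intensities at frame t (for simulating activity
#'   traces in a reporter channel).
#' @return List with \code{frames} (list of \code{volume_image}) and
#'   \code{truths} (list of per-frame \code{ground_truth}).
#' @export
render_series <- function(truth, n_frames, drift_per_frame = c(0, 0, 0),
                          voxel_size = default_voxel_size(),
                          noise = truth$spec$noise, seed = 1L,
                          extent = truth$spec$volume_extent,
                          origin = c(0, 0, 0), pi_series = NULL) {
  stopifnot(n_frames >= 1)
  pi0 <- component_intensities(truth)
  frames <- vector("list", n_frames)
  truths <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    tr <- truth
    shift <- (t - 1) * drift_per_frame
    pis <- if (is.null(pi_series)) pi0 else pi_series(t, pi0)
    for (i in seq_along(tr$components)) {
      tr$components[[i]]$mu <- tr$components[[i]]$mu + shift
      tr$components[[i]]$pi <- pis[i]
    }
    tr$displacement <- shift
    truths[[t]] <- tr
    frames[[t]] <- render_volume(tr, voxel_size, noise,
                                 seed = seed + t - 1L,
                                 extent = extent, origin = origin)
    frames[[t]]$time_index <- t
  }
  list(frames = frames, truths = truths)
}

#' Write ground truth components to CSV
#'
#' One row per component: peak intensity, centre (um) and the six unique
#' covariance entries. The format matches [write_mixture_csv()] so detected
#' mixtures and generator truth can be compared directly.
#'
#' @param truth a \code{ground_truth} (or \code{mixture_model}).
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_truth_csv <- function(truth, path) {
  df <- components_as_df(truth$components)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth / mixture CSV back into component form
#' @param path CSV written by [write_truth_csv()] or [write_mixture_csv()].
#' @return List of [gaussian_component()].
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path)
  df_as_components(df)
}

components_as_df <- function(comps) {
  if (!length(comps))
    return(data.frame(id = integer(0), pi = numeric(0), mu1 = numeric(0),
                      mu2 = numeric(0), mu3 = numeric(0), s11 = numeric(0),
                      s12 = numeric(0), s13 = numeric(0), s22 = numeric(0),
                      s23 = numeric(0), s33 = numeric(0)))
  do.call(rbind, lapply(seq_along(comps), function(i) {
    cc <- comps[[i]]
    data.frame(id = i, pi = cc$pi, mu1 = cc$mu[1], mu2 = cc$mu[2],
               mu3 = cc$mu[3], s11 = cc$sigma[1, 1], s12 = cc$sigma[1, 2],
               s13 = cc$sigma[1, 3], s22 = cc$sigma[2, 2],
               s23 = cc$sigma[2, 3], s33 = cc$sigma[3, 3])
  }))
}

df_as_components <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    s <- matrix(c(df$s11[i], df$s12[i], df$s13[i],
                  df$s12[i], df$s22[i], df$s23[i],
                  df$s13[i], df$s23[i], df$s33[i]), 3, 3)
    gaussian_component(pi = df$pi[i], mu = c(df$mu1[i], df$mu2[i], df$mu3[i]),
                       sigma = s)
  })
}

#' Write a JSON manifest describing a rendered scene
#' @param spec a [scene_spec()].
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_scene_manifest <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
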