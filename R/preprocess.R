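#' Parameters for Step-1 preprocessing
#'
#' @param median_radius half-width (voxels) of the 3D median denoising
#'   window; 0 disables. The window is a box of (2r+1)^3 voxels.
#' @param background_radius in-plane half-width (voxels) of the rolling-ball
#'   style background estimate (gray-scale box opening per x3 plane);
#'   0 disables.
#' @param blur_sigma Gaussian blur standard deviation per axis, voxels;
#'   0 disables.
#' @param threshold_method \code{"otsu"} or \code{"fixed"}.
#' @param fixed_threshold threshold intensity used when
#'   \code{threshold_method = "fixed"}.
#' @return An object of class \code{preprocess_params}.
#' @export
preprocess_params <- function(median_radius = 1, background_radius = 50,
                              blur_sigma = c(1, 1, 1),
                              threshold_method = c("otsu", "fixed"),
                              fixed_threshold = 0) {
  if (length(blur_sigma) == 1) blur_sigma <- rep(blur_sigma, 3)
  stopifnot(median_radius >= 0, background_radius >= 0, all(blur_sigma >= 0))
  structure(list(median_radius = as.integer(median_radius),
                 background_radius = as.integer(background_radius),
                 blur_sigma = as.numeric(blur_sigma),
                 threshold_method = match.arg(threshold_method),
                 fixed_threshold = fixed_threshold),
            class = "preprocess_params")
}

#' Subpixel translation registration by phase correlation
#'
#' Estimates the in-plane (x1, x2) rigid shift of each plane (or frame)
#' against a reference by cross-correlation, with optional subpixel
#' refinement via a locally upsampled discrete Fourier transform, and
#' returns the shift-corrected stack. Within a stack the middle x3 plane is
#' the reference; across time frames each frame is registered to the
#' previous corrected frame so drift does not accumulate within a stack.
#'
#' @param stack a \code{volume_image} (planes along x3) or list of 2D
#'   matrices.
#' @param upsample integer upsampling factor; 1 gives whole-voxel offsets,
#'   20 resolves 0.05-voxel shifts.
#' @param reference \code{"middle"} (register all planes to the middle one)
#'   or \code{"previous"} (chain, for time series).
#' @return List with \code{offsets} (n x 2 matrix of estimated (dx1, dx2)
#'   shifts of each plane relative to its reference) and \code{corrected}
#'   (same container as the input with shifts removed).
#' @export
register_translation <- function(stack, upsample = 1,
                                 reference = c("middle", "previous")) {
  reference <- match.arg(reference)
  is_vol <- is_volume_image(stack)
  planes <- if (is_vol) {
    lapply(seq_len(dim(stack$data)[3]), function(k) stack$data[, , k])
  } else stack
  n <- length(planes)
  d <- dim(planes[[1]])
  for (p in planes) if (!identical(dim(p), d))
    stop("all planes must have the same in-plane shape")
  offsets <- matrix(0, n, 2)
  corrected <- planes
  ref_idx <- if (reference == "middle") (n + 1L) %/% 2L else 1L
  ref <- planes[[ref_idx]]
  for (i in seq_len(n)) {
    if (i == ref_idx && reference == "middle") {
      offsets[i, ] <- c(0, 0)
    } else {
      if (reference == "previous" && i == 1) {
        offsets[i, ] <- c(0, 0)
      } else {
        offsets[i, ] <- phase_correlate(ref, planes[[i]], upsample)
        corrected[[i]] <- fourier_shift(planes[[i]], -offsets[i, ])
      }
    }
    if (reference == "previous") ref <- corrected[[i]]
  }
  if (is_vol) {
    out <- stack
    for (i in seq_len(n)) out$data[, , i] <- corrected[[i]]
    corrected <- out
  }
  list(offsets = offsets, corrected = corrected)
}

# Estimate the shift s such that moving(x + s) ~ ref(x), i.e. `moving` is
# `ref` translated by +s. Guizar-Sicairos style: integer peak of the phase
# correlation, then a matrix-multiply upsampled DFT in a 1.5-pixel
# neighbourhood of the peak.
phase_correlate <- function(ref, moving, upsample = 1) {
  d <- dim(ref)
  if (stats::sd(ref) == 0 || stats::sd(moving) == 0) {
    warning("degenerate (constant) plane in registration; offset set to 0")
    return(c(0, 0))
  }
  Fr <- stats::fft(ref)
  Fm <- stats::fft(moving)
  prod <- Fr * Conj(Fm)
  cc <- Re(stats::fft(prod, inverse = TRUE)) / length(prod)
  peak <- which.max(cc)
  p1 <- (peak - 1) %% d[1]
  p2 <- (peak - 1) %/% d[1]
  sh <- c(p1, p2)
  sh <- ifelse(sh > d / 2, sh - d, sh)
  if (upsample > 1) {
    # refine on a 1.5-pixel neighbourhood sampled at 1/upsample
    reg <- ceiling(upsample * 1.5)
    dftshift <- floor(reg / 2)
    off <- dftshift - sh * upsample
    cc_up <- Mod(upsampled_dft(Conj(prod), reg, upsample, off))
    mx <- which.max(cc_up)
    m1 <- (mx - 1) %% reg
    m2 <- (mx - 1) %/% reg
    sh <- sh + (c(m1, m2) - dftshift) / upsample
  }
  -sh
}

# Upsampled 2D inverse DFT of `data` over a region_size^2 window with the
# given per-axis offsets, via explicit kernel matrix products.
upsampled_dft <- function(data, region_size, upsample, offsets) {
  d <- dim(data)
  kern <- function(n, off) {
    shifted <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
    exp((-2i * pi / (n * upsample)) *
          outer(seq_len(region_size) - 1 - off, shifted))
  }
  k1 <- kern(d[1], offsets[1])
  k2 <- kern(d[2], offsets[2])
  k1 %*% data %*% t(k2)
}

# Translate a 2D image by a (possibly fractional) shift via Fourier phase.
fourier_shift <- function(img, shift) {
  d <- dim(img)
  f1 <- c(0:(ceiling(d[1] / 2) - 1), -(floor(d[1] / 2)):-1) / d[1]
  f2 <- c(0:(ceiling(d[2] / 2) - 1), -(floor(d[2] / 2)):-1) / d[2]
  ph <- exp(-2i * pi * (outer(f1 * shift[1], rep(1, d[2])) +
                          outer(rep(1, d[1]), f2 * shift[2])))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / length(img)
}

#' Step-1 preprocessing: denoise, subtract background, smooth
#'
#' Applies, in order: a 3D median filter (removes salt-and-pepper and
#' shot-like outliers), per-plane rolling-ball style background subtraction
#' (gray-scale box opening of half-width \code{background_radius} in x1/x2,
#' subtracted and clamped at zero), and a separable 3D Gaussian blur.
#'
#' @param v a \code{volume_image}.
#' @param p a [preprocess_params()].
#' @return A preprocessed \code{volume_image} of the same shape.
#' @export
preprocess_volume <- function(v, p = preprocess_params()) {
  stopifnot(is_volume_image(v), inherits(p, "preprocess_params"))
  d <- dim(v$data)
  if (p$median_radius * 2 + 1 > max(d))
    stop("median_radius larger than the volume")
  arr <- v$data
  if (p$median_radius > 0) {
    r <- pmin(rep(p$median_radius, 3), pmax(d - 1L, 0L))
    arr <- array(cpp_median_filter3d(as.numeric(arr), d, as.integer(r)),
                 dim = d)
  }
  if (p$background_radius > 0) {
    bg <- grey_open_inplane(arr, d, p$background_radius)
    arr <- pmax(arr - bg, 0)
  }
  if (any(p$blur_sigma > 0)) arr <- gaussian_blur3d(arr, p$blur_sigma)
  out <- v
  out$data <- arr
  out
}

# Per-plane gray-scale opening with a box structuring element: the classic
# rolling-ball background estimate with a flat structuring element.
grey_open_inplane <- function(arr, d, radius) {
  x <- as.numeric(arr)
  for (ax in 1:2) x <- cpp_minmax_axis(x, d, as.integer(radius), ax, FALSE)
  for (ax in 1:2) x <- cpp_minmax_axis(x, d, as.integer(radius), ax, TRUE)
  array(x, dim = d)
}

#' Separable Gaussian blur of a 3D array
#' @param arr numeric 3D array.
#' @param sigma per-axis standard deviation in voxels (length 3; 0 skips an
#'   axis).
#' @return Blurred array of the same shape.
#' @export
gaussian_blur3d <- function(arr, sigma) {
  d <- dim(arr)
  x <- as.numeric(arr)
  for (ax in 1:3) {
    if (sigma[ax] <= 0 || d[ax] == 1) next
    half <- max(1L, ceiling(4 * sigma[ax]))
    k <- stats::dnorm(-half:half, 0, sigma[ax])
    k <- k / sum(k)
    x <- cpp_convolve_axis(x, d, k, ax)
  }
  array(x, dim = d)
}

#' Global foreground threshold (Step-2 support)
#'
#' Removes obvious background voxels. Otsu's threshold (via \pkg{EBImage})
#' suits images whose foreground and background intensities form two clear
#' modes; the triangle threshold suits the typical fluorescence histogram
#' (a dominant background mode with a long bright tail) and cuts just above
#' the background, which preserves nuclei at the dim end of an
#' order-of-magnitude intensity range. Voxels with intensity greater than
#' or equal to the threshold are retained.
#'
#' @param v a \code{volume_image}.
#' @param method \code{"otsu"}, \code{"triangle"} or \code{"fixed"}.
#' @param fixed_threshold intensity cutoff for \code{method = "fixed"}.
#' @return Logical array of the volume's shape (TRUE = retained), with the
#'   threshold value in attribute \code{"threshold"}.
#' @export
global_threshold <- function(v, method = c("otsu", "triangle", "fixed"),
                             fixed_threshold = 0) {
  method <- match.arg(method)
  arr <- v$data
  if (method %in% c("otsu", "triangle")) {
    rng <- range(arr)
    if (rng[1] == rng[2])
      stop("automatic thresholding needs a non-constant volume")
    th <- auto_threshold(as.numeric(arr), method)
  } else {
    th <- fixed_threshold
    if (th > max(arr))
      warning("fixed threshold exceeds the volume maximum; mask is empty")
  }
  mask <- arr >= th
  attr(mask, "threshold") <- th
  mask
}

# Otsu's threshold of a numeric vector, delegated to EBImage on a rescaled
# copy. Returns a cutoff on the original intensity scale; values >= cutoff
# are foreground.
otsu_threshold <- function(x, levels = 1024L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  scaled <- (x - rng[1]) / (rng[2] - rng[1])
  img <- EBImage::Image(matrix(scaled, ncol = 1))
  th01 <- EBImage::otsu(img, range = c(0, 1), levels = levels)
  rng[1] + th01 * (rng[2] - rng[1])
}

# Triangle (Rosin) threshold: suited to skewed unimodal histograms where a
# dominant dim mode trails off into a bright tail — the shape of a
# segmented subimage containing a nucleus of any brightness. The threshold
# is the histogram bin farthest (perpendicularly) below the line joining
# the histogram peak to the far end of its longer tail. Unlike Otsu it does
# not cut between a dim and a bright object sharing one region.
triangle_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                nbins = levels)
  pk <- which.max(h)
  nz <- which(h > 0)
  # pick the longer tail side of the peak
  right <- (max(nz) - pk) >= (pk - min(nz))
  end <- if (right) max(nz) else min(nz)
  if (end == pk) return(rng[1])
  idx <- if (right) pk:end else end:pk
  # perpendicular distance of (i, h[i]) below the peak-to-end line
  x0 <- pk; y0 <- h[pk]; x1 <- end; y1 <- h[end]
  num <- abs((y1 - y0) * idx - (x1 - x0) * h[idx] + x1 * y0 - y1 * x0)
  best <- idx[which.max(num)]
  br[best + 1L]
}

# Dispatch on the automatic threshold method name.
auto_threshold <- function(x, method) {
  switch(method,
         otsu = otsu_threshold(x),
         triangle = triangle_threshold(x),
         stop("unknown threshold method: ", method))
}
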