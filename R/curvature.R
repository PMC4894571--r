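#' Principal curvatures of iso-intensity surfaces
#'
#' At each voxel the image's iso-intensity surface through that voxel is a
#' level set of the intensity function f. Its two principal curvatures are
#' the eigenvalues of the level-set shape operator
#' \deqn{S = -(I - n n^T) H (I - n n^T) / |g|,\quad n = g/|g|,}
#' restricted to the tangent plane, where g and H are the gradient and
#' Hessian of f. They are computed here in closed form from the implicit
#' mean curvature \eqn{(g^T H g - |g|^2 tr H) / (2 |g|^3)} and Gaussian
#' curvature \eqn{g^T H^* g / |g|^4} (H* the adjugate of H), with central
#' finite differences scaled by the per-axis voxel size so that all
#' curvatures are in physical units (1/um) and anisotropic sampling is
#' respected. The sign convention makes both curvatures positive everywhere
#' inside a single Gaussian blob (its level sets bulge away from the ridge);
#' the smaller curvature turns negative in the saddle between two blobs,
#' which is the signal exploited for clump splitting.
#'
#' Voxels where the gradient magnitude falls below \code{grad_epsilon}
#' (blob centres, flat background) carry no curvature claim and are marked
#' invalid. Volume borders use replicate padding and are flagged in
#' \code{boundary}. For single-plane (2D) volumes the level sets are curves
#' with a single curvature; both fields then carry the level-curve
#' curvature.
#'
#' @param v a \code{volume_image} (at least 3 voxels per axis in 3D).
#' @param grad_epsilon gradient-magnitude validity floor, intensity per um;
#'   default \code{1e-3 * max(v)}.
#' @return An object of class \code{curvature_field}: list with numeric
#'   arrays \code{kappa_min}, \code{kappa_max} (1/um), logical \code{valid}
#'   and \code{boundary}.
#' @export
principal_curvatures <- function(v, grad_epsilon = NULL) {
  stopifnot(is_volume_image(v))
  d <- dim(v$data)
  two_d <- d[3] == 1
  if (!two_d && any(d < 3))
    stop("3D volume must have at least 3 voxels per axis")
  if (two_d && any(d[1:2] < 3))
    stop("2D volume must have at least 3 voxels per in-plane axis")
  if (is.null(grad_epsilon)) grad_epsilon <- 1e-3 * max(v$data)
  f <- v$data
  h <- v$voxel_size

  g1 <- (shift_arr(f, 1, -1) - shift_arr(f, 1, 1)) / (2 * h[1])
  g2 <- (shift_arr(f, 2, -1) - shift_arr(f, 2, 1)) / (2 * h[2])
  g3 <- if (two_d) array(0, d) else
    (shift_arr(f, 3, -1) - shift_arr(f, 3, 1)) / (2 * h[3])
  h11 <- (shift_arr(f, 1, -1) - 2 * f + shift_arr(f, 1, 1)) / h[1]^2
  h22 <- (shift_arr(f, 2, -1) - 2 * f + shift_arr(f, 2, 1)) / h[2]^2
  h12 <- cross_diff(f, 1, 2, h)
  if (!two_d) {
    h33 <- (shift_arr(f, 3, -1) - 2 * f + shift_arr(f, 3, 1)) / h[3]^2
    h13 <- cross_diff(f, 1, 3, h)
    h23 <- cross_diff(f, 2, 3, h)
  }

  gn2 <- g1^2 + g2^2 + g3^2
  gn <- sqrt(gn2)
  valid <- gn > grad_epsilon
  safe <- pmax(gn, .Machine$double.eps)

  if (two_d) {
    # level-curve curvature, positive when curves bend away from the ridge
    kap <- -(h11 * g2^2 - 2 * g1 * g2 * h12 + h22 * g1^2) / safe^3
    kmin <- kmax <- kap
  } else {
    trH <- h11 + h22 + h33
    gHg <- g1 * (h11 * g1 + h12 * g2 + h13 * g3) +
      g2 * (h12 * g1 + h22 * g2 + h23 * g3) +
      g3 * (h13 * g1 + h23 * g2 + h33 * g3)
    # adjugate of the symmetric Hessian
    a11 <- h22 * h33 - h23^2
    a22 <- h11 * h33 - h13^2
    a33 <- h11 * h22 - h12^2
    a12 <- h13 * h23 - h12 * h33
    a13 <- h12 * h23 - h13 * h22
    a23 <- h12 * h13 - h11 * h23
    gAg <- g1 * (a11 * g1 + a12 * g2 + a13 * g3) +
      g2 * (a12 * g1 + a22 * g2 + a23 * g3) +
      g3 * (a13 * g1 + a23 * g2 + a33 * g3)
    mean_k <- (gHg - gn2 * trH) / (2 * safe^3)
    gauss_k <- gAg / safe^4
    disc <- sqrt(pmax(mean_k^2 - gauss_k, 0))
    kmin <- mean_k - disc
    kmax <- mean_k + disc
  }
  kmin[!valid] <- NA_real_
  kmax[!valid] <- NA_real_

  boundary <- array(FALSE, d)
  boundary[c(1, d[1]), , ] <- TRUE
  boundary[, c(1, d[2]), ] <- TRUE
  if (!two_d) boundary[, , c(1, d[3])] <- TRUE
  structure(list(kappa_min = kmin, kappa_max = kmax, valid = valid,
                 boundary = boundary, voxel_size = h, origin = v$origin),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("<curvature_field> %s voxels, %.1f%% valid\n",
              paste(dim(x$valid), collapse = " x "),
              100 * mean(x$valid)))
  invisible(x)
}

# Shift an array along `axis` by `by` voxels with replicate padding
# (by = -1 brings the next voxel's value to the current position).
shift_arr <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

cross_diff <- function(f, ax1, ax2, h) {
  (shift_arr(shift_arr(f, ax1, -1), ax2, -1) +
     shift_arr(shift_arr(f, ax1, 1), ax2, 1) -
     shift_arr(shift_arr(f, ax1, -1), ax2, 1) -
     shift_arr(shift_arr(f, ax1, 1), ax2, -1)) / (4 * h[ax1] * h[ax2])
}

#' Mask of voxels with negative smaller principal curvature
#'
#' These voxels sit in the saddle between overlapping blobs; removing them
#' from an under-segmented region makes the constituent nuclei separable.
#'
#' @param cf a \code{curvature_field}.
#' @param kappa_threshold cutoff (1/um), must be <= 0; the default 0 selects
#'   strict negativity, small negative values add noise robustness.
#' @return Logical array: valid, non-boundary voxels with
#'   \code{kappa_min < kappa_threshold} (the one-voxel volume border carries
#'   replicate-padding artifacts and makes no curvature claim).
#' @export
negative_mask <- function(cf, kappa_threshold = 0) {
  stopifnot(inherits(cf, "curvature_field"), kappa_threshold <= 0)
  m <- cf$valid & !cf$boundary & !is.na(cf$kappa_min) &
    (cf$kappa_min < kappa_threshold)
  m[is.na(m)] <- FALSE
  m
}
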