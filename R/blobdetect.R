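#' Detect local intensity peaks (watershed seeds)
#'
#' A voxel is a local peak if it is the unique maximum within an ellipsoidal
#' neighbourhood of the given per-axis radius (voxel units). If two
#' candidate voxels within the radius tie in intensity, only the
#' lexicographically smallest coordinate is kept, so two or more peaks never
#' coexist within one neighbourhood.
#'
#' @param v a \code{volume_image} (normally preprocessed).
#' @param radius neighbourhood radius in voxels; scalar or per-axis length 3.
#' @param mask optional logical array restricting where seeds may sit (e.g.
#'   the output of [global_threshold()]).
#' @return A \code{seed_set}: data frame with columns \code{x1, x2, x3}
#'   (voxel indices) and \code{intensity}.
#' @export
detect_peaks <- function(v, radius = 3, mask = NULL) {
  stopifnot(is_volume_image(v), all(radius >= 1))
  if (length(radius) == 1) radius <- rep(radius, 3)
  d <- dim(v$data)
  radius <- pmin(radius, d - 1L)
  radius[d == 1] <- 0
  m <- if (is.null(mask)) logical(0) else as.logical(mask)
  pts <- cpp_detect_peaks(as.numeric(v$data), d, as.numeric(radius), m)
  df <- data.frame(x1 = pts[, 1], x2 = pts[, 2], x3 = pts[, 3])
  df$intensity <- v$data[as.matrix(df)]
  # lexicographic order over (x1, x2, x3) for reproducible seed numbering
  df <- df[order(df$x1, df$x2, df$x3), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("seed_set", "data.frame")
  df
}

#' Seeded grayscale watershed segmentation
#'
#' Floods the intensity landscape downhill from the seeds (equivalently,
#' floods the inverted intensity uphill): every masked voxel connected to a
#' seed is assigned to exactly one seed's catchment basin, so the label
#' count equals the seed count and boundaries fall in intensity valleys.
#'
#' @param v a \code{volume_image}.
#' @param seeds a \code{seed_set} from [detect_peaks()], or an integer matrix
#'   of voxel coordinates (one row per seed).
#' @param mask logical array of voxels eligible for labeling; every seed
#'   must lie inside it.
#' @param connectivity 6 or 26 (face or full neighbourhood).
#' @return A \code{label_volume}; seed i keeps label i.
#' @export
seeded_watershed <- function(v, seeds, mask = NULL, connectivity = 26) {
  stopifnot(is_volume_image(v))
  d <- dim(v$data)
  coords <- as.matrix(seeds[, c("x1", "x2", "x3")])
  storage.mode(coords) <- "integer"
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  if (nrow(coords) && any(!mask[coords]))
    stop("seed outside mask")
  init <- array(0L, dim = d)
  init[coords] <- seq_len(nrow(coords))
  lab <- cpp_seeded_watershed(as.numeric(v$data), d, as.integer(init),
                              as.logical(mask), as.integer(connectivity))
  label_volume(array(lab, dim = d), v$voxel_size, origin = v$origin)
}

#' Remove small regions and strip per-region background
#'
#' Regions with fewer than \code{min_voxels} voxels are treated as noise and
#' deleted. Within each surviving region an automatic threshold (Otsu on
#' that region's own intensity histogram) strips its dim background voxels;
#' a region with a constant histogram is kept intact. Surviving regions are
#' relabeled densely 1..K in original label order.
#'
#' @param lv a \code{label_volume}.
#' @param v the aligned \code{volume_image} supplying intensities.
#' @param min_voxels minimum region volume (voxels) to survive.
#' @param region_threshold \code{"triangle"} (default; keeps a dim nucleus
#'   sharing a region with a bright one), \code{"otsu"} or \code{"none"}.
#' @return A cleaned \code{label_volume}.
#' @export
clean_regions <- function(lv, v, min_voxels = 27,
                          region_threshold = "triangle") {
  stopifnot(inherits(lv, "label_volume"), is_volume_image(v),
            identical(dim(lv$labels), dim(v$data)))
  lab <- lv$labels
  if (max(lab) == 0) return(lv)
  sizes <- tabulate(lab, nbins = max(lab))
  keep_ids <- which(sizes >= min_voxels)
  voxels_by_label <- split(seq_along(lab), as.vector(lab))
  out <- array(0L, dim = dim(lab))
  new_id <- 0L
  for (id in keep_ids) {
    sel <- voxels_by_label[[as.character(id)]]
    vals <- v$data[sel]
    if (region_threshold != "none" && length(unique(vals)) > 1) {
      th <- auto_threshold(vals, region_threshold)
      sel <- sel[vals >= th]
    }
    if (!length(sel)) next
    new_id <- new_id + 1L
    out[sel] <- new_id
  }
  label_volume(out, lv$voxel_size, origin = lv$origin)
}
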