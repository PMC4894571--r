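#' Parameters for curvature-driven clump splitting
#'
#' @param count_threshold a region is flagged as under-segmented when its
#'   number of qualifying negative-curvature voxels strictly exceeds this.
#' @param border_margin voxels closer than this (voxel units) to the region
#'   border are regarded as part of a correct segmentation and not counted.
#' @param connectivity 6 or 26, used for component analysis and watershed.
#' @param seed_merge_um suppression radius (um) for distance-transform
#'   maxima when re-seeding a flagged region (see [split_region()]).
#' @param seed_min_depth_um minimum distance-transform depth (um) for a
#'   re-seeding maximum, slightly below one voxel. A dim nucleus squeezed
#'   between the curvature sheet and the region border can be as little as
#'   one voxel deep, so this floor only rejects empty maxima; spurious
#'   shallow products are handled by the prominence merge instead.
#' @param prominence_um minimum basin prominence (um): after the second
#'   watershed, a product whose inscribed depth rises less than this above
#'   the saddle to a deeper neighbour is absorbed into it. Ripples along a
#'   plate-shaped remainder have sub-voxel prominence, while genuine nucleus
#'   cores rise well above their saddles, so a fraction of the voxel size
#'   separates the two.
#' @return An object of class \code{split_params}.
#' @export
split_params <- function(count_threshold = 10, border_margin = 1,
                         connectivity = 26, seed_merge_um = 1.0,
                         seed_min_depth_um = 0.2, prominence_um = 0.05) {
  stopifnot(count_threshold >= 1, border_margin >= 0,
            connectivity %in% c(6, 26), seed_merge_um > 0,
            seed_min_depth_um >= 0, prominence_um >= 0)
  structure(list(count_threshold = count_threshold,
                 border_margin = border_margin,
                 connectivity = as.integer(connectivity),
                 seed_merge_um = seed_merge_um,
                 seed_min_depth_um = seed_min_depth_um,
                 prominence_um = prominence_um),
            class = "split_params")
}

# Distance (voxel units, Euclidean) from each region voxel to the region
# border, where the border is the outermost voxel shell of the region.
region_border_distance <- function(region_mask) {
  d <- dim(region_mask)
  dist <- cpp_edt(as.logical(region_mask), d, c(1, 1, 1))
  array(dist, dim = d) - 1
}

#' Count qualifying negative-curvature voxels in a region
#'
#' A negative-curvature voxel counts toward the under-segmentation score of
#' a region only if (a) its connected component of negative-curvature voxels
#' inside the region reaches the region border (isolated interior islands
#' are noise), and (b) the voxel itself is farther than \code{border_margin}
#' from the border (voxels hugging the border belong to a correct
#' segmentation).
#'
#' @param region_mask logical array: the region (watershed subimage).
#' @param neg_mask logical array from [negative_mask()], same shape.
#' @param p a [split_params()].
#' @return List with \code{count} and the logical \code{qualifying} mask.
#' @export
qualifying_negative_voxels <- function(region_mask, neg_mask,
                                       p = split_params()) {
  stopifnot(identical(dim(region_mask), dim(neg_mask)))
  d <- dim(region_mask)
  nm <- region_mask & neg_mask
  if (!any(nm))
    return(list(count = 0L, qualifying = nm))
  border_dist <- region_border_distance(region_mask)
  comp <- array(cpp_label_components(as.logical(nm), d, p$connectivity),
                dim = d)
  # components touching the region border (distance 0 shell)
  touching <- unique(comp[comp > 0 & border_dist <= 0])
  qualifying <- nm & (comp %in% touching) & (border_dist > p$border_margin)
  qualifying <- array(qualifying, dim = d)
  list(count = sum(qualifying), qualifying = qualifying)
}

# Bounding box of a voxel set, padded by `pad` voxels and clamped to the
# array. Returns a list of three index vectors.
region_crop_idx <- function(vox, d, pad = 1L) {
  i <- (vox - 1L) %% d[1] + 1L
  j <- ((vox - 1L) %/% d[1]) %% d[2] + 1L
  k <- (vox - 1L) %/% (d[1] * d[2]) + 1L
  list(max(min(i) - pad, 1L):min(max(i) + pad, d[1]),
       max(min(j) - pad, 1L):min(max(j) + pad, d[2]),
       max(min(k) - pad, 1L):min(max(k) + pad, d[3]))
}

#' Flag under-segmented regions
#'
#' @param lv a \code{label_volume}.
#' @param neg_mask logical negative-curvature mask aligned to \code{lv}.
#' @param p a [split_params()].
#' @return Integer vector of flagged labels (qualifying count strictly
#'   greater than \code{count_threshold}).
#' @export
flag_undersegmented <- function(lv, neg_mask, p = split_params()) {
  stopifnot(inherits(lv, "label_volume"),
            identical(dim(lv$labels), dim(neg_mask)))
  d <- dim(lv$labels)
  vox_by_label <- label_voxel_lists(lv$labels)
  flagged <- integer(0)
  for (id_chr in names(vox_by_label)) {
    vox <- vox_by_label[[id_chr]]
    bb <- region_crop_idx(vox, d)
    lab_crop <- lv$labels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
    q <- qualifying_negative_voxels(
      lab_crop == as.integer(id_chr),
      neg_mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE], p)
    if (q$count > p$count_threshold)
      flagged <- c(flagged, as.integer(id_chr))
  }
  sort(flagged)
}

# Linear voxel indices of each positive label, as a named list.
label_voxel_lists <- function(lab) {
  pos <- which(lab > 0L)
  split(pos, as.vector(lab[pos]))
}

#' Split one under-segmented region
#'
#' The negative-curvature voxels are removed from the region; the remainder
#' is Euclidean-distance-transformed in physical units (anisotropic voxels
#' respected), seeds are placed one per plateau of the distance-transform
#' maxima, and the negated distance landscape is flooded by the seeded
#' watershed. Finally the removed voxels are reassigned to the geodesically
#' nearest resulting label so the split conserves the region's voxel set.
#'
#' @param region_mask logical array: the region to split.
#' @param neg_mask logical negative-curvature mask, same shape.
#' @param voxel_size per-axis voxel size, um.
#' @param connectivity 6 or 26.
#' @param seed_merge_um distance-transform maxima closer than this (um) to a
#'   higher maximum are suppressed before seeding the second watershed.
#'   Distinct nuclei centres are never closer than the packing floor
#'   (~1.5 um), so suppression up to that radius can only remove boundary
#'   roughness, never a real constituent's seed.
#' @param seed_min_depth_um,prominence_um seed-depth floor and basin
#'   prominence threshold, as in [split_params()].
#' @return A local \code{label_volume} covering exactly the region voxels
#'   with labels 1..K (K >= 1).
#' @export
split_region <- function(region_mask, neg_mask, voxel_size,
                         connectivity = 26, seed_merge_um = 1.0,
                         seed_min_depth_um = 0.2, prominence_um = 0.05) {
  stopifnot(any(region_mask))
  d <- dim(region_mask)
  remainder <- region_mask & !neg_mask
  if (!any(remainder)) {
    warning("region entirely covered by negative-curvature voxels; ",
            "returned unsplit")
    return(label_volume(array(as.integer(region_mask), dim = d), voxel_size))
  }
  dt <- array(cpp_edt(as.logical(remainder), d, as.numeric(voxel_size)),
              dim = d)
  # one seed per local maximum of the distance transform; exact ties within
  # the suppression radius (common: dt values are quantized by the voxel
  # geometry) keep only the lexicographically smallest voxel
  r_vox <- pmax(1, pmin(floor(seed_merge_um / voxel_size), d - 1L))
  r_vox[d == 1] <- 0
  pts <- cpp_detect_peaks(as.numeric(dt), d, as.numeric(r_vox),
                          as.logical(remainder))
  depth <- dt[pts]
  # exactly tied maxima further out are still one quantized plateau of a
  # single body, never two different nuclei; suppress them (lex order) out
  # to twice the radius
  if (nrow(pts) > 1) {
    um <- sweep(pts - 1, 2, voxel_size, "*")
    drop <- rep(FALSE, nrow(pts))
    for (a in seq_len(nrow(pts) - 1)) for (b in (a + 1):nrow(pts)) {
      if (abs(depth[a] - depth[b]) < 1e-9 &&
          sum((um[a, ] - um[b, ])^2) < (2 * seed_merge_um)^2)
        drop[b] <- TRUE  # pts are in lexicographic order already
    }
    pts <- pts[!drop, , drop = FALSE]
    depth <- depth[!drop]
  }
  keep <- which(depth >= seed_min_depth_um)
  if (!length(keep)) keep <- which.max(depth)  # at least one seed survives
  seeds <- array(0L, dim = d)
  for (s in seq_along(keep))
    seeds[pts[keep[s], 1], pts[keep[s], 2], pts[keep[s], 3]] <- s
  lab <- cpp_seeded_watershed(as.numeric(dt), d, as.integer(seeds),
                              as.logical(remainder),
                              as.integer(connectivity))
  lab <- merge_shallow_basins(array(lab, dim = d), dt, prominence_um)
  # hand the removed saddle voxels to the nearest label, keeping coverage
  lab <- cpp_nearest_label(as.integer(lab), d, as.numeric(voxel_size),
                           as.logical(region_mask))
  label_volume(array(lab, dim = d), voxel_size)
}

# Merge watershed basins whose inscribed depth rises less than
# `prominence_um` above the saddle shared with a deeper neighbour (the
# h-maxima rule applied post hoc). A genuine nucleus core is a basin of its
# own; ripples along a plate-shaped remainder are not.
merge_shallow_basins <- function(lab, dt, prominence_um) {
  repeat {
    K <- max(lab)
    if (K < 2) break
    depth <- vapply(seq_len(K), function(i) max(dt[lab == i]), numeric(1))
    # saddle height between each adjacent label pair (6-neighbourhood scan)
    saddle <- matrix(-Inf, K, K)
    d <- dim(lab)
    for (axis in 1:3) {
      if (d[axis] == 1) next
      n <- d[axis]
      idx_a <- idx_b <- lapply(d, seq_len)
      idx_a[[axis]] <- 1:(n - 1)
      idx_b[[axis]] <- 2:n
      la <- do.call(`[`, c(list(lab), idx_a, list(drop = FALSE)))
      lb <- do.call(`[`, c(list(lab), idx_b, list(drop = FALSE)))
      da <- do.call(`[`, c(list(dt), idx_a, list(drop = FALSE)))
      db <- do.call(`[`, c(list(dt), idx_b, list(drop = FALSE)))
      sel <- la > 0 & lb > 0 & la != lb
      if (!any(sel)) next
      pr <- data.frame(i = pmin(la[sel], lb[sel]),
                       j = pmax(la[sel], lb[sel]),
                       s = pmin(da[sel], db[sel]))
      agg <- stats::aggregate(s ~ i + j, data = pr, FUN = max)
      for (r in seq_len(nrow(agg)))
        saddle[agg$i[r], agg$j[r]] <- max(saddle[agg$i[r], agg$j[r]],
                                          agg$s[r])
    }
    prom <- outer(depth, depth, pmin) - saddle
    prom[!is.finite(saddle)] <- Inf
    if (min(prom) >= prominence_um) break
    pair <- which(prom == min(prom), arr.ind = TRUE)[1, ]
    # absorb the shallower basin into the deeper one
    from <- pair[which.min(depth[pair])]
    into <- setdiff(pair, from)[1]
    lab[lab == from] <- into
    lab[lab > from] <- lab[lab > from] - 1L
  }
  lab
}

#' Apply clump splitting to every flagged region of a segmentation
#'
#' @param lv a \code{label_volume} from Step 2.
#' @param neg_mask logical negative-curvature mask aligned to \code{lv}.
#' @param p a [split_params()].
#' @return List with the relabeled \code{label_volume} (dense labels, split
#'   products inserted at their parent's position in label order),
#'   \code{flagged} (labels that were split) and \code{n_added} (number of
#'   extra regions created).
#' @export
split_undersegmented <- function(lv, neg_mask, p = split_params()) {
  flagged <- flag_undersegmented(lv, neg_mask, p)
  d <- dim(lv$labels)
  vox_by_label <- label_voxel_lists(lv$labels)
  out <- array(0L, dim = d)
  new_id <- 0L
  for (id_chr in names(vox_by_label)) {
    id <- as.integer(id_chr)
    vox <- vox_by_label[[id_chr]]
    if (id %in% flagged) {
      bb <- region_crop_idx(vox, d)
      lab_crop <- lv$labels[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
      sub <- split_region(lab_crop == id,
                          neg_mask[bb[[1]], bb[[2]], bb[[3]], drop = FALSE],
                          lv$voxel_size, p$connectivity, p$seed_merge_um,
                          p$seed_min_depth_um, p$prominence_um)
      sub_lab <- sub$labels
      for (s in seq_len(max(sub_lab))) {
        new_id <- new_id + 1L
        tmp <- out[bb[[1]], bb[[2]], bb[[3]], drop = FALSE]
        tmp[sub_lab == s] <- new_id
        out[bb[[1]], bb[[2]], bb[[3]]] <- tmp
      }
    } else {
      new_id <- new_id + 1L
      out[vox] <- new_id
    }
  }
  list(labels = label_volume(out, lv$voxel_size, origin = lv$origin),
       flagged = flagged, n_added = new_id - max(lv$labels))
}
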