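# Brute-force peak oracle: voxel p is a peak iff nothing in its ellipsoidal
# neighbourhood beats it, ties resolved toward the lexicographically
# smallest coordinate.
brute_peaks <- function(arr, radius) {
  d <- dim(arr)
  out <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    ok <- TRUE
    for (dz in -radius:radius) for (dy in -radius:radius)
      for (dx in -radius:radius) {
        if ((dx / radius)^2 + (dy / radius)^2 + (dz / radius)^2 > 1 + 1e-12)
          next
        ii <- i + dx; jj <- j + dy; kk <- k + dz
        if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
            kk < 1 || kk > d[3]) next
        if (dx == 0 && dy == 0 && dz == 0) next
        if (arr[ii, jj, kk] > arr[i, j, k]) { ok <- FALSE; break }
        if (arr[ii, jj, kk] == arr[i, j, k] &&
            (ii < i || (ii == i && (jj < j || (jj == j && kk < k))))) {
          ok <- FALSE; break
        }
      }
    if (ok) out <- rbind(out, c(i, j, k))
  }
  out
}

test_that("peak detection matches the brute-force neighbourhood-max oracle", {
  set.seed(21)
  arr <- array(0, c(12, 10, 8))
  arr[4, 5, 4] <- 10
  arr[9, 5, 4] <- 10          # second equal blob, > 2 * radius away
  arr[4, 5, 6] <- 10          # tied voxel within radius of the first
  arr <- gaussian_blur3d(arr, c(0.8, 0.8, 0.8)) + 1e-6 * array(
    runif(prod(c(12, 10, 8))), c(12, 10, 8))
  v <- volume_image(arr, c(1, 1, 1))
  got <- detect_peaks(v, 2)
  want <- brute_peaks(arr, 2)
  want <- want[order(want[, 1], want[, 2], want[, 3]), , drop = FALSE]
  expect_equal(as.matrix(got[, 1:3]), want, ignore_attr = TRUE)
})

test_that("a single blob yields exactly one peak at its argmax", {
  v <- isotropic_blob()
  pk <- detect_peaks(v, 3)
  expect_equal(nrow(pk), 1)
  am <- which(v$data == max(v$data), arr.ind = TRUE)[1, ]
  expect_equal(as.integer(pk[1, 1:3]), as.integer(am))
})

test_that("tied plateau voxels within the radius keep only the lexicographically smallest", {
  arr <- array(0, c(9, 9, 9))
  arr[4, 5, 5] <- 7
  arr[6, 5, 5] <- 7   # within radius 3 of the first, equal height
  v <- volume_image(arr, c(1, 1, 1))
  pk <- detect_peaks(v, 3, mask = arr > 0)
  expect_equal(nrow(pk), 1)
  expect_equal(as.integer(pk[1, 1:3]), c(4L, 5L, 5L))
})

test_that("peaks are invariant to a constant intensity offset", {
  set.seed(22)
  arr <- gaussian_blur3d(array(runif(14 * 12 * 10), c(14, 12, 10)),
                         c(1, 1, 1))
  v1 <- volume_image(arr, c(1, 1, 1))
  v2 <- volume_image(arr + 57.3, c(1, 1, 1))
  expect_equal(detect_peaks(v1, 2)[, 1:3], detect_peaks(v2, 2)[, 1:3])
})

test_that("peak recall is perfect on well-separated equal-brightness scenes", {
  sp <- scene_spec(n_nuclei = 30, volume_extent = c(40, 32, 22),
                   spacing_mean = 7, spacing_sd = 0.8, min_separation = 6,
                   intensity_decades = 0, noise = NULL, seed = 13)
  tr <- sample_scene(sp)
  v <- render_volume(tr, noise = NULL)
  pk <- detect_peaks(v, 3, v$data > 1)
  pk_um <- cbind((pk$x1 - 1) * v$voxel_size[1], (pk$x2 - 1) * v$voxel_size[2],
                 (pk$x3 - 1) * v$voxel_size[3])
  rep <- match_points(pk_um, component_centers(tr))
  expect_equal(compute_indices(rep)$tp_rate, 1.0)
})

test_that("seeded watershed floods masks completely, one basin per seed", {
  # one seed, one connected mask
  arr <- array(1, c(6, 6, 6))
  v <- volume_image(arr, c(1, 1, 1))
  mask <- array(TRUE, c(6, 6, 6))
  seeds <- data.frame(x1 = 3L, x2 = 3L, x3 = 3L)
  lv <- seeded_watershed(v, seeds, mask)
  expect_true(all(lv$labels == 1L))

  # two seeds in two disjoint components
  mask2 <- array(FALSE, c(10, 6, 6))
  mask2[1:4, , ] <- TRUE
  mask2[7:10, , ] <- TRUE
  seeds2 <- data.frame(x1 = c(2L, 9L), x2 = c(3L, 3L), x3 = c(3L, 3L))
  lv2 <- seeded_watershed(v = volume_image(array(1, c(10, 6, 6)),
                                           c(1, 1, 1)),
                          seeds2, mask2)
  expect_true(all(lv2$labels[1:4, , ] == 1L))
  expect_true(all(lv2$labels[7:10, , ] == 2L))
  expect_true(all(lv2$labels[5:6, , ] == 0L))

  expect_error(seeded_watershed(v, data.frame(x1 = 1L, x2 = 1L, x3 = 1L),
                                array(FALSE, c(6, 6, 6))), "seed")
})

test_that("watershed boundaries fall in the intensity valley of the doublet", {
  v <- doublet_volume()
  ax <- voxel_axes(v)
  j0 <- which(abs(ax[[2]]) < 1e-9)
  k0 <- which(abs(ax[[3]]) < 1e-9)
  i1 <- which(abs(ax[[1]] + 1) < 1e-9)
  i2 <- which(abs(ax[[1]] - 2) < 1e-9)
  seeds <- data.frame(x1 = c(i1, i2), x2 = j0, x3 = k0)
  mask <- v$data >= 1
  lv <- seeded_watershed(v, seeds, mask)
  # 1D oracle: the intensity minimum along the centre line
  line <- v$data[i1:i2, j0, k0]
  cut <- i1 + which.min(line) - 1L
  for (i in i1:(cut - 1L))
    expect_equal(lv$labels[i, j0, k0], 1L)
  for (i in (cut + 1L):i2)
    expect_equal(lv$labels[i, j0, k0], 2L)
  expect_equal(max(lv$labels), 2L)
  expect_true(all(lv$labels[!mask] == 0L))
})

test_that("label count equals seed count and labels stay inside the mask", {
  set.seed(23)
  for (rep in 1:3) {
    arr <- gaussian_blur3d(array(runif(16 * 14 * 10), c(16, 14, 10)),
                           c(1.5, 1.5, 1.5))
    v <- volume_image(arr, c(1, 1, 1))
    mask <- arr > quantile(arr, 0.3)
    pk <- detect_peaks(v, 2, mask)
    lv <- seeded_watershed(v, pk, mask)
    expect_equal(sort(unique(as.vector(lv$labels[mask]))),
                 seq_len(nrow(pk)))
    expect_true(all(lv$labels[!mask] == 0L))
  }
})

test_that("region cleanup drops small regions, keeps constants, and applies the stated threshold rule", {
  arr <- array(0, c(12, 8, 6))
  arr[2:3, 2:3, 2:3] <- 5          # 8 voxels: below min_voxels
  arr[6:11, 2:7, 1:6] <- 2         # large uniform region
  lab <- array(0L, c(12, 8, 6))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[6:11, 2:7, 1:6] <- 2L
  v <- volume_image(arr, c(1, 1, 1))
  lv <- label_volume(lab, c(1, 1, 1))
  out <- clean_regions(lv, v, min_voxels = 27)
  expect_equal(n_regions(out), 1)
  expect_true(all(out$labels[6:11, 2:7, 1:6] == 1L))  # constant region kept

  # a Gaussian core with a flat dim halo: retained set must equal the
  # brute-force application of the per-region Otsu rule
  arr2 <- array(0, c(15, 15, 9))
  for (i in 1:15) for (j in 1:15) for (k in 1:9)
    arr2[i, j, k] <- 100 * exp(-((i - 8)^2 + (j - 8)^2 + (k - 5)^2) / 6)
  halo <- arr2 > 0 & arr2 < 1
  arr2[halo] <- 0.5
  lab2 <- array(1L, c(15, 15, 9))
  v2 <- volume_image(arr2, c(1, 1, 1))
  out2 <- clean_regions(label_volume(lab2, c(1, 1, 1)), v2,
                        min_voxels = 27, region_threshold = "otsu")
  th <- nucdetect:::otsu_threshold(as.numeric(arr2))
  expect_identical(out2$labels == 1L, array(arr2 >= th, dim = dim(arr2)))
})
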