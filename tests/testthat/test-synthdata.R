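test_that("scene sampling places nuclei inside the volume, deterministically", {
  sp1 <- scene_spec(n_nuclei = 1, volume_extent = c(10, 10, 10), seed = 3)
  tr1 <- sample_scene(sp1)
  expect_length(tr1$components, 1)
  expect_true(all(tr1$components[[1]]$mu >= 0 &
                    tr1$components[[1]]$mu <= c(10, 10, 10)))

  sp50 <- scene_spec(n_nuclei = 50, volume_extent = c(30, 25, 18), seed = 9)
  a <- sample_scene(sp50)
  b <- sample_scene(sp50)
  expect_identical(a, b)
  cen <- component_centers(a)
  expect_true(all(sweep(cen, 2, sp50$volume_extent, "/") >= 0 &
                    sweep(cen, 2, sp50$volume_extent, "/") <= 1))
})

test_that("a two-nucleus scene with zero spacing spread sits at the exact target distance", {
  tr <- sample_scene(scene_spec(n_nuclei = 2, volume_extent = c(20, 20, 20),
                                spacing_sd = 0, seed = 5))
  expect_equal(as.numeric(dist(component_centers(tr))), 4.30,
               tolerance = 1e-9)
})

test_that("infeasible packings fail loudly", {
  sp <- scene_spec(n_nuclei = 100, volume_extent = c(4, 4, 4), seed = 1)
  expect_error(sample_scene(sp, max_tries = 100), "infeasible")
})

test_that("nearest-neighbour statistics of a 200-nucleus scene match the target", {
  tr <- sample_scene(scene_spec(n_nuclei = 200, seed = 1))
  cen <- component_centers(tr)
  D <- as.matrix(dist(cen))
  diag(D) <- Inf
  nn <- apply(D, 1, min)
  expect_gt(mean(nn), 4.30 * 0.85)
  expect_lt(mean(nn), 4.30 * 1.15)
  expect_gte(min(nn), 1.5 - 1e-9)   # hard packing floor
})

test_that("peak intensities span the requested decades, log-uniformly", {
  tr <- sample_scene(scene_spec(n_nuclei = 200, seed = 2))
  pis <- component_intensities(tr)
  expect_lte(max(pis), 200)
  expect_gte(min(pis), 20)
  expect_gt(max(pis) / min(pis), 5)  # spread actually used
})

test_that("noiseless renders equal the analytic mixture at every voxel", {
  tr <- sample_scene(scene_spec(n_nuclei = 3, volume_extent = c(8, 7, 6),
                                seed = 4, noise = NULL))
  v <- render_volume(tr, voxel_size = c(0.5, 0.5, 0.5), noise = NULL)
  ax <- voxel_axes(v)
  # independent scalar oracle at a grid of probe voxels
  for (i in seq(1, dim(v$data)[1], by = 3))
    for (j in seq(1, dim(v$data)[2], by = 4))
      for (k in seq(1, dim(v$data)[3], by = 4)) {
        want <- mixture_value_at(tr$components,
                                 c(ax[[1]][i], ax[[2]][j], ax[[3]][k]))
        expect_equal(v$data[i, j, k], want, tolerance = 1e-10)
      }
})

test_that("the doublet render reproduces the two-component sum at the bright centre", {
  v <- doublet_volume()
  ax <- voxel_axes(v)
  i <- which(abs(ax[[1]] + 1) < 1e-9)
  j <- which(abs(ax[[2]]) < 1e-9)
  k <- which(abs(ax[[3]]) < 1e-9)
  f2 <- 40 * exp(-0.5 * (3 / (1.10 * 0.9))^2)  # dim tail at the bright centre
  expect_equal(v$data[i, j, k], 120 + f2, tolerance = 1e-9)
})

test_that("empty truth renders pure background and argmax sits at the nearest grid point", {
  empty <- structure(list(components = list(), spec = list(noise = NULL)),
                     class = "ground_truth")
  v0 <- render_volume(empty, voxel_size = c(0.5, 0.5, 0.5),
                      noise = list(background_level = 7), seed = 1,
                      extent = c(5, 5, 5))
  expect_true(all(v0$data == 7))

  tr <- structure(
    list(components = list(gaussian_component(50, c(2.26, 3.1, 1.4),
                                              diag(0.8^2, 3))),
         spec = list(noise = NULL)),
    class = "ground_truth")
  v1 <- render_volume(tr, voxel_size = c(0.3, 0.3, 0.3), noise = NULL,
                      extent = c(6, 6, 4))
  am <- which(v1$data == max(v1$data), arr.ind = TRUE)[1, ]
  ax <- voxel_axes(v1)
  nearest <- vapply(1:3, function(a)
    which.min(abs(ax[[a]] - tr$components[[1]]$mu[a])), integer(1))
  expect_equal(as.integer(am), nearest)
})

test_that("renders with the same seed are bit-identical; noise changes with the seed", {
  tr <- sample_scene(scene_spec(n_nuclei = 4, volume_extent = c(10, 8, 6),
                                seed = 6))
  v1 <- render_volume(tr, seed = 33)
  v2 <- render_volume(tr, seed = 33)
  v3 <- render_volume(tr, seed = 34)
  expect_identical(v1$data, v2$data)
  expect_false(identical(v1$data, v3$data))
})

test_that("time series drift the truth rigidly and degenerate to a single render", {
  tr <- sample_scene(scene_spec(n_nuclei = 2, volume_extent = c(10, 8, 6),
                                spacing_sd = 0, seed = 8, noise = NULL))
  still <- render_series(tr, n_frames = 3, drift_per_frame = c(0, 0, 0),
                         noise = NULL)
  expect_identical(still$frames[[1]]$data, still$frames[[3]]$data)

  one <- render_series(tr, n_frames = 1, noise = NULL)
  direct <- render_volume(tr, noise = NULL)
  expect_identical(one$frames[[1]]$data, direct$data)

  mv <- render_series(tr, n_frames = 5, drift_per_frame = c(0.2, 0, 0),
                      noise = NULL)
  am0 <- which(mv$frames[[1]]$data == max(mv$frames[[1]]$data),
               arr.ind = TRUE)[1, ]
  am4 <- which(mv$frames[[5]]$data == max(mv$frames[[5]]$data),
               arr.ind = TRUE)[1, ]
  shift_um <- unname(am4[1] - am0[1]) * mv$frames[[1]]$voxel_size[1]
  expect_equal(shift_um, 0.8, tolerance = 0.25)  # one voxel of rounding
  expect_equal(mv$truths[[5]]$components[[1]]$mu,
               tr$components[[1]]$mu + c(0.8, 0, 0))
})

test_that("ground truth round-trips through CSV and manifests are written", {
  tr <- sample_scene(scene_spec(n_nuclei = 5, volume_extent = c(12, 10, 8),
                                seed = 10))
  f <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(tr, f)
  back <- read_truth_csv(f)
  expect_length(back, 5)
  for (i in 1:5) {
    expect_equal(back[[i]]$mu, tr$components[[i]]$mu)
    expect_equal(back[[i]]$sigma, tr$components[[i]]$sigma)
    expect_equal(back[[i]]$pi, tr$components[[i]]$pi)
  }
  mf <- withr::local_tempfile(fileext = ".json")
  write_scene_manifest(tr$spec, mf)
  expect_equal(jsonlite::fromJSON(mf)$n_nuclei, 5)
})
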