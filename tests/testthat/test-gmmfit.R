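test_that("component and mixture constructors enforce their invariants", {
  expect_error(gaussian_component(-1, c(0, 0, 0), diag(1, 3)))
  expect_error(gaussian_component(1, c(0, 0, 0), diag(c(1, -1, 1))))
  bad <- diag(1, 3)
  bad[1, 2] <- 0.5
  expect_error(gaussian_component(1, c(0, 0, 0), bad), "symmetric")
  m <- mixture_model(list(gaussian_component(1, c(0, 0, 0), diag(1, 3))))
  expect_s3_class(m, "mixture_model")
})

test_that("initialization puts one component per label at the weighted centroid", {
  sc <- scene20()
  truth1 <- structure(list(components = sc$truth$components[1],
                           spec = sc$truth$spec), class = "ground_truth")
  v <- render_volume(truth1, noise = NULL, extent = c(24, 20, 14))
  lab <- array(0L, dim(v$data))
  lab[v$data > 0.05 * max(v$data)] <- 1L
  init <- initialize_mixture(label_volume(lab, v$voxel_size), v)
  expect_length(init$components, 1)
  err <- abs(init$components[[1]]$mu - truth1$components[[1]]$mu)
  expect_lt(max(err), 0.5 * max(v$voxel_size))
  expect_equal(init$components[[1]]$pi, max(v$data))

  # uniform intensity: centroid is geometric
  arr <- array(0, c(10, 10, 10))
  arr[2:5, 3:6, 4:7] <- 4
  vu <- volume_image(arr, c(1, 1, 1))
  labu <- array(0L, dim(arr))
  labu[arr > 0] <- 1L
  initu <- initialize_mixture(label_volume(labu, c(1, 1, 1)), vu)
  expect_equal(initu$components[[1]]$mu, c(mean(1:4), mean(2:5), mean(3:6)))

  # two labels come out in label order
  labu[8:9, 8:9, 8:9] <- 2L
  arr[8:9, 8:9, 8:9] <- 1
  init2 <- initialize_mixture(label_volume(labu, c(1, 1, 1)),
                              volume_image(arr, c(1, 1, 1)))
  expect_length(init2$components, 2)
  expect_lt(init2$components[[1]]$mu[1], init2$components[[2]]$mu[1])
})

test_that("a fit initialized at the truth of a noiseless render stays there", {
  comps <- list(gaussian_component(80, c(3, 3, 3),
                                   diag(c(1.1, 0.9, 1.2)^2)))
  tr <- structure(list(components = comps, spec = list(noise = NULL)),
                  class = "ground_truth")
  v <- render_volume(tr, voxel_size = c(0.25, 0.25, 0.25), noise = NULL,
                     extent = c(6, 6, 6))
  fit <- fit_mixture(v, mixture_model(comps), fit_options(max_iter = 3))
  expect_lt(max(abs(fit$components[[1]]$mu - c(3, 3, 3))), 1e-3)
  expect_lt(abs(fit$components[[1]]$pi - 80) / 80, 1e-3)
  expect_lt(fit$fit_sse, 1e-4 * sum(v$data^2))
})

test_that("the doublet fit recovers centres and peaks from a perturbed start", {
  v <- doublet_volume()
  init <- mixture_model(list(
    gaussian_component(100, c(-1.1, 0.1, 0), diag(1.1^2, 3)),
    gaussian_component(60, c(2.1, -0.1, 0.1), diag(1.1^2, 3))))
  fit <- fit_mixture(v, init, fit_options())
  cen <- component_centers(fit)
  expect_lt(max(abs(cen[1, ] - c(-1, 0, 0))), 0.1)
  expect_lt(max(abs(cen[2, ] - c(2, 0, 0))), 0.1)
  pis <- component_intensities(fit)
  expect_lt(abs(pis[1] - 120) / 120, 0.05)
  expect_lt(abs(pis[2] - 40) / 40, 0.05)
})

test_that("the joint intensity step matches a dense normal-equations oracle", {
  sc <- scene20()
  comps <- sc$truth$components[1:6]
  v <- render_volume(structure(list(components = comps,
                                    spec = sc$truth$spec),
                               class = "ground_truth"),
                     voxel_size = c(0.4, 0.4, 0.4), noise = NULL,
                     extent = c(24, 20, 14))
  axes <- voxel_axes(v)
  y <- as.numeric(v$data)
  got <- nucdetect:::solve_pi_linear(y, comps, axes, dim(v$data), Inf)
  # oracle: dense design matrix of unit Gaussians, solved by normal equations
  A <- sapply(comps, function(cc) {
    g <- cc
    g$pi <- 1
    as.numeric(evaluate_mixture(mixture_model(list(g)), v))
  })
  want <- solve(crossprod(A), crossprod(A, y))
  expect_equal(got, as.numeric(want), tolerance = 1e-6)
  expect_equal(got, vapply(comps, function(cc) cc$pi, numeric(1)),
               tolerance = 1e-6)
})

test_that("SSE decreases monotonically across outer iterations", {
  sc <- scene20()
  sub <- sc$truth$components[1:5]
  v <- render_volume(structure(list(components = sub, spec = sc$truth$spec),
                               class = "ground_truth"),
                     noise = NULL, extent = c(24, 20, 14))
  init <- mixture_model(lapply(sub, function(cc) {
    cc$mu <- cc$mu + c(0.3, -0.2, 0.2)
    cc$pi <- cc$pi * 1.5
    cc$sigma <- diag(1.1^2, 3)
    cc
  }))
  fit <- fit_mixture(v, init, fit_options(max_iter = 10))
  trace <- attr(fit, "sse_trace")
  expect_gt(length(trace), 2)
  expect_true(all(diff(trace) <= 1e-6 * trace[1]))
})

test_that("covariance eigenvalues respect the configured bounds", {
  # a tiny bright speck would drive sigma below the floor without clamping
  arr <- array(0, c(15, 15, 15))
  arr[8, 8, 8] <- 100
  arr <- gaussian_blur3d(arr, c(0.6, 0.6, 0.6))
  v <- volume_image(arr, c(0.24, 0.24, 0.252))
  init <- mixture_model(list(gaussian_component(
    50, c(7, 7, 7) * 0.24, diag(1.1^2, 3))))
  fit <- fit_mixture(v, init, fit_options(max_iter = 6))
  hr <- sqrt(eigen(fit$components[[1]]$sigma, symmetric = TRUE)$values)
  expect_true(all(hr >= 0.3 - 1e-9 & hr <= 3 + 1e-9))
})

test_that("merging removes the dimmer of a too-close pair and is idempotent", {
  sc <- scene20()
  far <- mixture_model(list(
    gaussian_component(50, c(5, 5, 5), diag(1, 3)),
    gaussian_component(80, c(10, 5, 5), diag(1, 3))))
  v <- render_volume(structure(list(components = far$components,
                                    spec = sc$truth$spec),
                               class = "ground_truth"),
                     noise = NULL, extent = c(24, 20, 14))
  out <- merge_close_components(far, v, fit_options(merge_cutoff = 2))
  expect_false(out$merged)
  expect_length(out$model$components, 2)

  near_truth <- list(gaussian_component(90, c(6, 6, 6), diag(1, 3)))
  vn <- render_volume(structure(list(components = near_truth,
                                     spec = sc$truth$spec),
                                class = "ground_truth"),
                      noise = NULL, extent = c(24, 20, 14))
  dup <- mixture_model(list(
    gaussian_component(60, c(5.7, 6, 6), diag(1, 3)),
    gaussian_component(40, c(6.7, 6, 6), diag(1, 3))))
  out2 <- merge_close_components(fit_mixture(vn, dup,
                                             fit_options(max_iter = 2)),
                                 vn, fit_options(merge_cutoff = 2))
  expect_true(out2$merged)
  expect_length(out2$model$components, 1)
  expect_gt(out2$model$components[[1]]$pi, 50)  # survivor was the brighter

  again <- merge_close_components(out2$model, vn,
                                  fit_options(merge_cutoff = 2))
  expect_false(again$merged)
  expect_equal(component_centers(again$model),
               component_centers(out2$model), tolerance = 1e-9)
})

test_that("three mutually close components merge until all pairs clear the cutoff", {
  sc <- scene20()
  truth <- list(gaussian_component(100, c(8, 8, 8), diag(1.2, 3)))
  v <- render_volume(structure(list(components = truth,
                                    spec = sc$truth$spec),
                               class = "ground_truth"),
                     noise = NULL, extent = c(24, 20, 14))
  trip <- mixture_model(list(
    gaussian_component(50, c(7.4, 8, 8), diag(1, 3)),
    gaussian_component(60, c(8.3, 8, 8), diag(1, 3)),
    gaussian_component(40, c(8, 8.8, 8), diag(1, 3))))
  out <- merge_close_components(fit_mixture(v, trip,
                                            fit_options(max_iter = 2)),
                                v, fit_options(merge_cutoff = 1.4))
  cen <- component_centers(out$model)
  if (nrow(cen) > 1) {
    D <- as.matrix(dist(cen))
    diag(D) <- Inf
    expect_gte(min(D), 1.4)
  }
  expect_true(out$merged)
})

test_that("channel scalings are recovered with shapes frozen", {
  sc <- scene20()
  sub <- sc$truth$components[1:6]
  tr <- structure(list(components = sub, spec = sc$truth$spec),
                  class = "ground_truth")
  v <- render_volume(tr, noise = NULL, extent = c(24, 20, 14))
  m <- mixture_model(sub)

  # exact scaling of the detection channel
  v2 <- v
  v2$data <- 0.37 * v$data
  got <- estimate_channel_scalings(v2, m)
  expect_equal(got, 0.37 * vapply(sub, function(cc) cc$pi, numeric(1)),
               tolerance = 1e-3)  # windowed evaluation truncates the tails

  # independently drawn peaks in the other channel
  set.seed(31)
  pi_other <- runif(6, 10, 120)
  tr2 <- tr
  for (i in seq_along(tr2$components)) tr2$components[[i]]$pi <- pi_other[i]
  v3 <- render_volume(tr2, noise = NULL, extent = c(24, 20, 14))
  got2 <- estimate_channel_scalings(v3, m)
  expect_lt(max(abs(got2 - pi_other) / pi_other), 0.05)

  # pure noise: intensities near zero
  set.seed(32)
  vn <- v
  vn$data <- array(abs(rnorm(length(v$data), 0, 0.5)), dim(v$data))
  got3 <- estimate_channel_scalings(vn, m)
  expect_lt(max(got3), 0.05 * min(pi_other))
  expect_true(all(got3 >= 0))
})

test_that("the 4-sigma evaluation window changes the SSE by less than 0.1%", {
  sc <- scene20()
  sub <- sc$truth$components[1:10]
  tr <- structure(list(components = sub, spec = sc$truth$spec),
                  class = "ground_truth")
  v <- render_volume(tr, noise = NULL, extent = c(24, 20, 14))
  # an imperfect model, so the SSE is a meaningful quantity to compare
  rough <- mixture_model(lapply(sub, function(cc) {
    cc$mu <- cc$mu + 0.3
    cc$sigma <- diag(1.1^2, 3)
    cc
  }))
  m_win <- evaluate_mixture(rough, v, support_radius = 4)
  m_full <- evaluate_mixture(rough, v, support_radius = Inf)
  sse_win <- sum((v$data - m_win)^2)
  sse_full <- sum((v$data - m_full)^2)
  expect_lt(abs(sse_win - sse_full), 1e-3 * sse_full)
})

test_that("mixtures round-trip through CSV and JSON", {
  sc <- scene20()
  m <- mixture_model(sc$truth$components[1:4], fit_sse = 12.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_mixture_csv(m, f)
  back <- read_mixture_csv(f)
  expect_equal(component_centers(back), component_centers(m))
  expect_equal(back$fit_sse, 12.5)
  fj <- withr::local_tempfile(fileext = ".json")
  write_mixture_json(m, fj)
  expect_length(jsonlite::fromJSON(fj, simplifyVector = FALSE)$components, 4)
})
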