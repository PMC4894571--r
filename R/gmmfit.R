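#' One nucleus model: an unnormalized trivariate Gaussian
#'
#' A nucleus's fluorescence profile is modeled as
#' \code{pi * exp(-t(x - mu) Sigma^-1 (x - mu) / 2)}: peak height \code{pi}
#' (intensity units), centre \code{mu} (um) and covariance \code{Sigma}
#' (um^2) whose eigenvalue square roots are the per-axis half-radii.
#'
#' @param pi positive peak intensity scaling factor.
#' @param mu numeric length-3 centre, um.
#' @param sigma symmetric positive-definite 3x3 covariance, um^2.
#' @return An object of class \code{gaussian_component}.
#' @export
gaussian_component <- function(pi, mu, sigma) {
  mu <- as.numeric(mu)
  stopifnot(length(pi) == 1, pi > 0, length(mu) == 3,
            is.matrix(sigma), all(dim(sigma) == c(3, 3)))
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(abs(sigma)))
    stop("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("sigma must be positive definite")
  structure(list(pi = as.numeric(pi), mu = mu, sigma = (sigma + t(sigma)) / 2),
            class = "gaussian_component")
}

#' Ordered set of Gaussian components with fit bookkeeping
#'
#' @param components list of [gaussian_component()].
#' @param channel_scalings optional matrix of per-channel peak intensities
#'   (rows = channels, columns = components); the detection channel's pi
#'   values live in the components themselves.
#' @param fit_sse sum of squared residuals of the last fit (NA before
#'   fitting).
#' @return An object of class \code{mixture_model}.
#' @export
mixture_model <- function(components, channel_scalings = NULL,
                          fit_sse = NA_real_) {
  stopifnot(is.list(components))
  if (!is.null(channel_scalings))
    stopifnot(ncol(channel_scalings) == length(components))
  structure(list(components = components,
                 channel_scalings = channel_scalings,
                 fit_sse = fit_sse),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("<mixture_model> %d components, SSE = %.6g\n",
              length(x$components), x$fit_sse))
  invisible(x)
}

#' Options controlling the mixture fit
#'
#' @param max_iter maximum outer alternations.
#' @param rel_tol stop when the relative SSE improvement of an outer
#'   iteration falls below this.
#' @param merge_cutoff centre distance (um) below which two components are
#'   deemed the same nucleus. Distinct nuclei never sit closer than the
#'   physical packing floor (~1.5 um, the sum of two typical half-radii at
#'   contact), so the default stays just below it: everything closer is a
#'   duplicate fit of one nucleus, and nothing farther is ever merged.
#' @param default_sigma initial covariance for new components, um^2; the
#'   default is the isotropic typical half-radius 1.10 um.
#' @param support_radius per-component evaluation window half-width, in
#'   multiples of the per-axis standard deviation; \code{Inf} evaluates on
#'   the whole volume.
#' @param sigma_floor,sigma_ceiling bounds on covariance eigenvalue square
#'   roots (um), preventing component collapse or explosion.
#' @param refine_maxit Levenberg-Marquardt iteration cap of each
#'   per-component refinement.
#' @param refine_radius window half-width (multiples of sigma) used during
#'   per-component refinement; localization information lives within ~3
#'   standard deviations, so a tighter window than \code{support_radius}
#'   loses nothing while costing much less.
#' @param freeze \code{"none"} (fit mu and Sigma), \code{"all"} (mu only;
#'   Sigma frozen, tracking default) or \code{"rotation"} (mu plus an
#'   orthogonal factor; Sigma eigenvalues frozen).
#' @return An object of class \code{fit_options}.
#' @export
fit_options <- function(max_iter = 30, rel_tol = 1e-5, merge_cutoff = 1.4,
                        default_sigma = diag(1.10^2, 3),
                        support_radius = 4, sigma_floor = 0.3,
                        sigma_ceiling = 3.0, refine_maxit = 10,
                        refine_radius = 3,
                        freeze = c("none", "all", "rotation")) {
  stopifnot(max_iter >= 1, rel_tol > 0, merge_cutoff > 0,
            support_radius > 0, sigma_floor > 0,
            sigma_ceiling > sigma_floor, refine_radius > 0)
  structure(list(max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 merge_cutoff = merge_cutoff, default_sigma = default_sigma,
                 support_radius = support_radius, sigma_floor = sigma_floor,
                 sigma_ceiling = sigma_ceiling,
                 refine_maxit = as.integer(refine_maxit),
                 refine_radius = min(refine_radius, support_radius),
                 freeze = match.arg(freeze)),
            class = "fit_options")
}

# ---- evaluation helpers ----------------------------------------------------

# Window (linear indices + centred coordinate matrix) of one component.
component_window <- function(comp, axes, support_radius) {
  d <- vapply(axes, length, integer(1))
  sd_ax <- sqrt(pmax(diag(comp$sigma), 1e-12))
  rng <- lapply(1:3, function(a) {
    if (!is.finite(support_radius)) return(seq_len(d[a]))
    w <- which(axes[[a]] >= comp$mu[a] - support_radius * sd_ax[a] &
                 axes[[a]] <= comp$mu[a] + support_radius * sd_ax[a])
    if (!length(w)) w <- which.min(abs(axes[[a]] - comp$mu[a]))
    w
  })
  n1 <- length(rng[[1]]); n2 <- length(rng[[2]]); n3 <- length(rng[[3]])
  lin <- rep(rng[[1]], times = n2 * n3) +
    (rep(rep(rng[[2]], each = n1), times = n3) - 1L) * d[1] +
    (rep(rng[[3]], each = n1 * n2) - 1L) * d[1] * d[2]
  pts <- cbind(rep(axes[[1]][rng[[1]]], times = n2 * n3),
               rep(rep(axes[[2]][rng[[2]]], each = n1), times = n3),
               rep(axes[[3]][rng[[3]]], each = n1 * n2))
  list(lin = lin, pts = pts)
}

# Unit-amplitude Gaussian values exp(-q/2) at the window points.
unit_gaussian <- function(pts, mu, sigma) {
  pc <- sweep(pts, 2, mu)
  si <- tryCatch(chol2inv(chol(sigma)), error = function(e) solve(sigma))
  q <- rowSums((pc %*% si) * pc)
  exp(-0.5 * q)
}

# Render the full model array of a component list.
render_model <- function(comps, axes, d, support_radius) {
  model <- numeric(prod(d))
  for (cc in comps) {
    w <- component_window(cc, axes, support_radius)
    model[w$lin] <- model[w$lin] + cc$pi * unit_gaussian(w$pts, cc$mu,
                                                         cc$sigma)
  }
  array(model, dim = d)
}

#' Evaluate a mixture model on a volume's voxel grid
#'
#' @param m a \code{mixture_model} (or \code{ground_truth}).
#' @param v a \code{volume_image} defining the grid.
#' @param support_radius evaluation window, multiples of sigma.
#' @return Numeric array of model intensities, same shape as \code{v$data}.
#' @export
evaluate_mixture <- function(m, v, support_radius = Inf) {
  axes <- voxel_axes(v)
  render_model(m$components, axes, dim(v$data), support_radius)
}

# ---- initialization --------------------------------------------------------

#' Initialize a mixture from a label volume
#'
#' One component per label: the centre is the intensity-weighted centroid of
#' the label's voxels (um), the covariance starts at
#' \code{opts$default_sigma}, and the peak starts at the region's maximum
#' intensity. Component order is label order.
#'
#' @param lv a \code{label_volume} (clump-splitting output).
#' @param v the aligned \code{volume_image}.
#' @param opts a [fit_options()].
#' @return A \code{mixture_model} (empty when \code{lv} has no labels).
#' @export
initialize_mixture <- function(lv, v, opts = fit_options()) {
  stopifnot(inherits(lv, "label_volume"), is_volume_image(v),
            identical(dim(lv$labels), dim(v$data)))
  axes <- voxel_axes(v)
  vox_by_label <- label_voxel_lists(lv$labels)
  d <- dim(v$data)
  two_d <- d[3] == 1
  comps <- lapply(vox_by_label, function(vox) {
    wts <- pmax(v$data[vox], 0)
    if (sum(wts) <= 0) wts <- rep(1, length(vox))
    i <- (vox - 1L) %% d[1] + 1L
    j <- ((vox - 1L) %/% d[1]) %% d[2] + 1L
    k <- (vox - 1L) %/% (d[1] * d[2]) + 1L
    mu <- c(sum(wts * axes[[1]][i]), sum(wts * axes[[2]][j]),
            sum(wts * axes[[3]][k])) / sum(wts)
    gaussian_component(pi = max(v$data[vox]), mu = mu,
                       sigma = opts$default_sigma)
  })
  names(comps) <- NULL
  mixture_model(comps)
}

# ---- the alternating least-squares fit -------------------------------------

#' Least-squares fit of a Gaussian mixture to a volume
#'
#' Minimizes the sum of squared residuals
#' \code{sum_x (v(x) - sum_k f_k(x))^2} over all peak intensities, centres
#' and covariances by alternate optimization: (a) with centres and
#' covariances held, all peaks solve a joint linear least-squares problem
#' exactly; (b) each component's centre and covariance is refined by local
#' Levenberg-Marquardt on its own residual window with the other components
#' frozen, the covariance parameterized through its Cholesky factor to stay
#' positive definite (eigenvalue square roots clamped to
#' \code{[sigma_floor, sigma_ceiling]}). Every step is accepted only if it
#' does not increase the SSE, so the SSE trace is monotone nonincreasing.
#'
#' @param v a preprocessed \code{volume_image}.
#' @param init a nonempty \code{mixture_model} (e.g. from
#'   [initialize_mixture()]).
#' @param opts a [fit_options()].
#' @return The fitted \code{mixture_model}; \code{fit_sse} holds the final
#'   SSE and attribute \code{"sse_trace"} the per-iteration values.
#' @export
fit_mixture <- function(v, init, opts = fit_options()) {
  stopifnot(is_volume_image(v), inherits(init, "mixture_model"))
  if (!length(init$components)) return(init)
  d <- dim(v$data)
  two_d <- d[3] == 1
  axes <- voxel_axes(v)
  y <- as.numeric(v$data)
  comps <- init$components
  model <- as.numeric(render_model(comps, axes, d, opts$support_radius))
  sse <- sum((y - model)^2)
  trace <- sse
  events <- character(0)
  # per-component convergence bookkeeping: a component that stopped moving
  # is skipped until the joint intensity step disturbs it again
  settled <- rep(FALSE, length(comps))
  for (iter in seq_len(opts$max_iter)) {
    sse_before <- sse
    # (a) joint linear solve for all peak intensities
    pi_old <- vapply(comps, function(cc) cc$pi, numeric(1))
    sol <- solve_pi_linear(y, comps, axes, d, opts$support_radius,
                           return_model = TRUE)
    pi_new <- sol$pi
    cand <- comps
    for (k in seq_along(cand)) cand[[k]]$pi <- pi_new[k]
    model_cand <- sol$model
    sse_cand <- sum((y - model_cand)^2)
    if (sse_cand <= sse) {
      comps <- cand; model <- model_cand; sse <- sse_cand
      settled <- settled & (abs(pi_new - pi_old) <= 1e-3 * pmax(pi_old,
                                                                1e-12))
    }
    # (b) per-component nonlinear refinement of mu (and Sigma)
    for (k in seq_along(comps)) {
      if (settled[k]) next
      ref <- refine_component(comps[[k]], y, model, axes, d, opts, two_d)
      if (!is.null(ref$events)) events <- c(events, ref$events)
      if (ref$accepted) {
        comps[[k]] <- ref$comp
        model <- ref$model
        sse <- sse + ref$delta_sse
        if (-ref$delta_sse <= opts$rel_tol * max(sse, 1e-12))
          settled[k] <- TRUE
      } else {
        settled[k] <- TRUE
      }
    }
    sse <- sum((y - model)^2)  # refresh against drift of increments
    trace <- c(trace, sse)
    if (sse_before - sse < opts$rel_tol * max(sse_before, .Machine$double.eps))
      break
  }
  out <- mixture_model(comps, channel_scalings = init$channel_scalings,
                       fit_sse = sse)
  attr(out, "sse_trace") <- trace
  attr(out, "events") <- events
  out
}

# Exact joint linear least squares for the peak intensities given shapes.
# Negative solutions are handled by one-at-a-time active-set elimination and
# floored at a tiny positive value (a component never carries pi <= 0).
solve_pi_linear <- function(y, comps, axes, d, support_radius,
                            return_model = FALSE) {
  K <- length(comps)
  wins <- lapply(comps, function(cc) {
    w <- component_window(cc, axes, support_radius)
    list(lin = w$lin, g = unit_gaussian(w$pts, cc$mu, cc$sigma))
  })
  A <- Matrix::sparseMatrix(
    i = unlist(lapply(wins, `[[`, "lin")),
    j = rep(seq_len(K), vapply(wins, function(w) length(w$lin), integer(1))),
    x = unlist(lapply(wins, `[[`, "g")),
    dims = c(length(y), K))
  G <- as.matrix(Matrix::crossprod(A))
  b <- as.numeric(Matrix::crossprod(A, y))
  active <- rep(TRUE, K)
  pi_hat <- numeric(K)
  for (pass in seq_len(K)) {
    ridge <- diag(1e-10 * max(diag(G)), sum(active))
    sol <- tryCatch(solve(G[active, active, drop = FALSE] + ridge,
                          b[active]),
                    error = function(e) rep(NA_real_, sum(active)))
    if (any(is.na(sol))) break
    pi_hat[active] <- sol
    neg <- active & (pi_hat < 0)
    if (!any(neg)) break
    worst <- which(active)[which.min(pi_hat[active])]
    active[worst] <- FALSE
    pi_hat[worst] <- 0
  }
  floor_val <- 1e-9 * max(abs(b), 1)
  pi_hat <- pmax(pi_hat, floor_val)
  if (!return_model) return(pi_hat)
  list(pi = pi_hat, model = as.numeric(A %*% pi_hat))
}

# Local Levenberg-Marquardt refinement of one component against the target
# t = residual + own contribution, over the component's window. Returns the
# updated component, updated full model vector and the SSE change; the step
# is accepted only when the window SSE does not increase.
refine_component <- function(comp, y, model, axes, d, opts, two_d) {
  sr <- opts$support_radius
  rr <- if (is.null(opts$refine_radius)) sr else opts$refine_radius
  w <- component_window(comp, axes, rr)
  g_old <- comp$pi * unit_gaussian(w$pts, comp$mu, comp$sigma)
  target <- y[w$lin] - model[w$lin] + g_old
  sse_old <- sum((target - g_old)^2)
  freeze <- opts$freeze
  events <- NULL

  par0 <- encode_params(comp, freeze, two_d)
  # the LM driver evaluates the residual and the Jacobian at the same
  # parameter vector back-to-back; share the Gaussian evaluation between them
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  state_at <- function(par) {
    # note: the LM driver updates `par` in place at the C level, so the
    # cached copy must be a genuine duplicate for the comparison to work
    if (!is.null(cache$par) && identical(as.numeric(par), cache$par))
      return(cache$st)
    dec <- decode_params(par, comp, freeze, two_d, opts)
    pc <- w$pts
    pc[, 1] <- pc[, 1] - dec$mu[1]
    pc[, 2] <- pc[, 2] - dec$mu[2]
    pc[, 3] <- pc[, 3] - dec$mu[3]
    L <- t(chol(dec$sigma))
    z <- t(forwardsolve(L, t(pc)))          # z = L^-1 (x - mu)
    f <- dec$pi * exp(-0.5 * rowSums(z^2))
    st <- list(dec = dec, L = L, z = z, f = f)
    cache$par <- as.numeric(par) + 0
    cache$st <- st
    st
  }
  resid_fn <- function(par) target - state_at(par)$f
  # analytic Jacobian of the residual for the mu / Cholesky parameterization
  # (numeric differences for the rotation mode, which has few users)
  jac_fn <- if (freeze == "rotation") NULL else function(par) {
    st <- state_at(par)
    L <- st$L; z <- st$z; f <- st$f
    wv <- t(backsolve(t(L), t(z)))          # w = Sigma^-1 (x - mu)
    Jmu <- -f * wv                          # d r / d mu  = -f w
    if (freeze == "all")
      return(if (two_d) Jmu[, 1:2, drop = FALSE] else Jmu)
    if (two_d) {
      J <- matrix(0, length(f), 5)
      J[, 1:2] <- Jmu[, 1:2]
      J[, 3] <- -f * wv[, 1] * z[, 1] * L[1, 1]  # log L11
      J[, 4] <- -f * wv[, 2] * z[, 2] * L[2, 2]  # log L22
      J[, 5] <- -f * wv[, 2] * z[, 1]            # L21
      J
    } else {
      J <- matrix(0, length(f), 9)
      J[, 1:3] <- Jmu
      J[, 4] <- -f * wv[, 1] * z[, 1] * L[1, 1]
      J[, 5] <- -f * wv[, 2] * z[, 2] * L[2, 2]
      J[, 6] <- -f * wv[, 3] * z[, 3] * L[3, 3]
      J[, 7] <- -f * wv[, 2] * z[, 1]            # L21
      J[, 8] <- -f * wv[, 3] * z[, 1]            # L31
      J[, 9] <- -f * wv[, 3] * z[, 2]            # L32
      J
    }
  }
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = opts$refine_maxit))),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$par)))
    return(list(accepted = FALSE, events = "refinement failed"))
  dec <- decode_params(fit$par, comp, freeze, two_d, opts)
  if (any(!is.finite(dec$mu)) || any(!is.finite(dec$sigma)))
    return(list(accepted = FALSE, events = "refinement diverged"))
  if (freeze == "none") {
    cl <- clamp_sigma(dec$sigma, opts$sigma_floor, opts$sigma_ceiling, two_d)
    if (cl$clamped) events <- c(events, "sigma eigenvalue clamped")
    dec$sigma <- cl$sigma
  }
  new_comp <- comp
  new_comp$mu <- dec$mu
  new_comp$sigma <- dec$sigma
  w_new <- component_window(new_comp, axes, sr)
  g_new <- new_comp$pi * unit_gaussian(w_new$pts, new_comp$mu,
                                       new_comp$sigma)
  # window SSE comparison on the union of old and new windows
  model_wo <- model
  model_wo[w$lin] <- model_wo[w$lin] - g_old
  lin_union <- union(w$lin, w_new$lin)
  res_old <- y[lin_union] - model[lin_union]
  model_new <- model_wo
  model_new[w_new$lin] <- model_new[w_new$lin] + g_new
  res_new <- y[lin_union] - model_new[lin_union]
  delta <- sum(res_new^2) - sum(res_old^2)
  if (!is.finite(delta) || delta > 0)
    return(list(accepted = FALSE, events = events))
  list(accepted = TRUE, comp = new_comp, model = model_new,
       delta_sse = delta, events = events)
}

encode_params <- function(comp, freeze, two_d) {
  if (freeze == "all") {
    return(if (two_d) comp$mu[1:2] else comp$mu)
  }
  if (freeze == "rotation") {
    return(c(if (two_d) comp$mu[1:2] else comp$mu, 0, 0, 0))
  }
  if (two_d) {
    L <- t(chol(comp$sigma[1:2, 1:2]))
    c(comp$mu[1:2], log(L[1, 1]), log(L[2, 2]), L[2, 1])
  } else {
    L <- t(chol(comp$sigma))
    c(comp$mu, log(diag(L)), L[2, 1], L[3, 1], L[3, 2])
  }
}

decode_params <- function(par, comp, freeze, two_d, opts) {
  mu <- comp$mu
  if (two_d) mu[1:2] <- par[1:2] else mu <- par[1:3]
  nmu <- if (two_d) 2L else 3L
  sigma <- comp$sigma
  if (freeze == "rotation") {
    ang <- par[nmu + 1:3]
    R <- rot3(ang)
    sigma <- R %*% comp$sigma %*% t(R)
    sigma <- (sigma + t(sigma)) / 2
  } else if (freeze == "none") {
    if (two_d) {
      L <- matrix(0, 2, 2)
      L[1, 1] <- exp(par[3]); L[2, 2] <- exp(par[4]); L[2, 1] <- par[5]
      sigma[1:2, 1:2] <- L %*% t(L)
    } else {
      L <- matrix(0, 3, 3)
      diag(L) <- exp(par[4:6])
      L[2, 1] <- par[7]; L[3, 1] <- par[8]; L[3, 2] <- par[9]
      sigma <- L %*% t(L)
    }
  }
  list(pi = comp$pi, mu = mu, sigma = sigma)
}

rot3 <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Clamp covariance eigenvalue square roots into [floor, ceiling] um.
clamp_sigma <- function(sigma, floor_um, ceiling_um, two_d = FALSE) {
  ei <- eigen(sigma, symmetric = TRUE)
  hr <- sqrt(pmax(ei$values, 0))
  hr_cl <- pmin(pmax(hr, floor_um), ceiling_um)
  if (two_d) hr_cl[3] <- max(hr[3], 1e-3)  # out-of-plane axis not clamped
  clamped <- any(hr_cl != hr)
  sig <- ei$vectors %*% diag(hr_cl^2) %*% t(ei$vectors)
  list(sigma = (sig + t(sig)) / 2, clamped = clamped)
}

# ---- merging ---------------------------------------------------------------

#' Merge components that converged onto the same nucleus
#'
#' While any pair of centres is closer than \code{opts$merge_cutoff} (um),
#' the dimmer member of the closest pair is removed and the mixture refit;
#' repeated watershed application tends to over-segment, and two fitted
#' centres this close represent one nucleus.
#'
#' @param m a fitted \code{mixture_model}.
#' @param v the \code{volume_image} that was fit.
#' @param opts a [fit_options()].
#' @return List with the possibly reduced \code{model} and logical
#'   \code{merged}.
#' @export
merge_close_components <- function(m, v, opts = fit_options()) {
  merged <- FALSE
  # quick refits between removals; one full fit once no pair violates
  quick <- opts
  quick$max_iter <- min(opts$max_iter, 3L)
  repeat {
    removed_any <- FALSE
    repeat {
      K <- length(m$components)
      if (K < 2) break
      cen <- component_centers(m)
      D <- as.matrix(stats::dist(cen))
      diag(D) <- Inf
      if (min(D) >= opts$merge_cutoff) break
      pair <- which(D == min(D), arr.ind = TRUE)[1, ]
      pis <- component_intensities(m)
      drop_k <- pair[which.min(pis[pair])]
      m$components[[drop_k]] <- NULL
      m <- fit_mixture(v, m, quick)
      merged <- TRUE
      removed_any <- TRUE
    }
    if (!removed_any) break
    m <- fit_mixture(v, m, opts)  # settle fully, then re-check distances
  }
  list(model = m, merged = merged)
}

# ---- other channels --------------------------------------------------------

#' Estimate per-component intensities in another channel
#'
#' With centres and covariances frozen at the detection-channel fit, the
#' peak intensities in another (aligned) channel solve a linear least
#' squares problem; negative solutions are clamped to zero.
#'
#' @param other a \code{volume_image} aligned to the detection channel.
#' @param m a fitted \code{mixture_model}.
#' @param support_radius evaluation window, multiples of sigma.
#' @return Numeric vector of per-component peak intensities in the channel.
#' @export
estimate_channel_scalings <- function(other, m, support_radius = 4) {
  stopifnot(is_volume_image(other), inherits(m, "mixture_model"))
  if (!length(m$components)) return(numeric(0))
  axes <- voxel_axes(other)
  pi_ch <- solve_pi_linear(as.numeric(other$data), m$components, axes,
                           dim(other$data), support_radius)
  pmax(pi_ch, 0)
}

# ---- I/O -------------------------------------------------------------------

#' Write a fitted mixture to CSV
#'
#' Same column layout as [write_truth_csv()] (id, pi, centre, six covariance
#' entries) plus the fit SSE, so detected mixtures and generator truth
#' compare directly.
#'
#' @param m a \code{mixture_model}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_mixture_csv <- function(m, path) {
  df <- components_as_df(m$components)
  df$sse <- m$fit_sse
  if (!is.null(m$channel_scalings))
    for (ch in seq_len(nrow(m$channel_scalings)))
      df[[paste0("pi_ch", ch)]] <- m$channel_scalings[ch, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a mixture written by [write_mixture_csv()]
#' @param path CSV path.
#' @return A \code{mixture_model}.
#' @export
read_mixture_csv <- function(path) {
  df <- utils::read.csv(path)
  m <- mixture_model(df_as_components(df))
  if ("sse" %in% names(df) && nrow(df)) m$fit_sse <- df$sse[1]
  m
}

#' Write a mixture as JSON
#' @param m a \code{mixture_model}.
#' @param path output JSON path.
#' @return Invisibly, the path.
#' @export
write_mixture_json <- function(m, path) {
  comps <- lapply(m$components, function(cc)
    list(pi = cc$pi, mu = cc$mu, sigma = as.vector(cc$sigma)))
  jsonlite::write_json(list(components = comps, fit_sse = m$fit_sse),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
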