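#' Options controlling frame-to-frame tracking
#'
#' @param fit a [fit_options()]; its \code{freeze} field selects how nucleus
#'   sizes are conserved: \code{"all"} (default; covariances fully frozen)
#'   or \code{"rotation"} (orientation free, eigenvalues frozen).
#' @param register logical; estimate the whole-animal in-plane translation
#'   between consecutive frames (phase correlation of the x3 maximum
#'   projections) and pre-shift the warm start by it.
#' @param upsample registration upsampling factor.
#' @param max_step_um guard: a component whose centre moves farther than
#'   this in one frame, or leaves the volume, is reset to its previous
#'   state and flagged.
#' @return An object of class \code{track_options}.
#' @export
track_options <- function(fit = fit_options(freeze = "all", max_iter = 8),
                          register = TRUE, upsample = 10,
                          max_step_um = 3) {
  if (fit$freeze == "none")
    fit$freeze <- "all"  # tracking must conserve nucleus sizes
  structure(list(fit = fit, register = register, upsample = upsample,
                 max_step_um = max_step_um),
            class = "track_options")
}

#' Track a fitted mixture into the next frame
#'
#' The converged mixture of the current frame is the warm start for the next
#' frame: peak intensities and centres are refit while the covariance
#' eigenvalues (the nucleus sizes) stay exactly those of the input.
#' Components that diverge (centre leaving the volume or jumping farther
#' than \code{max_step_um}) are reset to their previous state and flagged.
#'
#' @param prev the fitted \code{mixture_model} of the current frame.
#' @param v_next the next frame's preprocessed \code{volume_image}.
#' @param opts a [track_options()].
#' @param v_prev optional previous frame (enables registration pre-shift).
#' @return The fitted \code{mixture_model} for the next frame; attribute
#'   \code{"flagged"} lists components that were reset.
#' @export
track_frame <- function(prev, v_next, opts = track_options(),
                        v_prev = NULL) {
  stopifnot(inherits(prev, "mixture_model"), is_volume_image(v_next))
  init <- prev
  if (opts$register && !is.null(v_prev)) {
    proj_prev <- apply(v_prev$data, 1:2, max)
    proj_next <- apply(v_next$data, 1:2, max)
    off <- phase_correlate(proj_prev, proj_next, opts$upsample)
    shift_um <- c(off * v_next$voxel_size[1:2], 0)
    for (k in seq_along(init$components))
      init$components[[k]]$mu <- init$components[[k]]$mu + shift_um
  }
  fitted <- fit_mixture(v_next, init, opts$fit)
  lo <- v_next$origin
  hi <- v_next$origin + (dim(v_next$data) - 1) * v_next$voxel_size
  flagged <- integer(0)
  for (k in seq_along(fitted$components)) {
    mu <- fitted$components[[k]]$mu
    step <- sqrt(sum((mu - prev$components[[k]]$mu)^2))
    out_of_volume <- any(mu < lo - 1e-9) || any(mu > hi + 1e-9)
    if (out_of_volume || step > opts$max_step_um) {
      fitted$components[[k]] <- prev$components[[k]]
      flagged <- c(flagged, k)
    }
  }
  attr(fitted, "flagged") <- flagged
  fitted
}

#' Track a mixture through a time series and extract intensity traces
#'
#' Chains [track_frame()] over all frames, warm-starting each frame at the
#' previous converged fit. Component count and order are fixed for the whole
#' run, so component k at frame t always descends from component k at frame
#' t-1 (identity conservation by construction). After each frame, per-
#' component intensities are estimated in every additional channel with
#' shapes frozen ([estimate_channel_scalings()]).
#'
#' @param frames list of \code{volume_image}: the detection channel, one per
#'   time point (preprocessed or raw; preprocessing is the caller's choice).
#' @param init the detection result for frame 1 (a fitted
#'   \code{mixture_model}).
#' @param opts a [track_options()].
#' @param channels optional named list; each element is a list of
#'   \code{volume_image} parallel to \code{frames} for one other channel.
#' @return An object of class \code{trajectory}: list with \code{models}
#'   (per-frame mixtures), \code{centers} (frames x components x 3 array,
#'   um), \code{intensity} (frames x components detection-channel peaks),
#'   \code{channel_intensity} (named list of frames x components matrices)
#'   and \code{flagged} (per-frame reset components).
#' @export
track_series <- function(frames, init, opts = track_options(),
                         channels = NULL) {
  stopifnot(length(frames) >= 1, inherits(init, "mixture_model"))
  n_t <- length(frames)
  K <- length(init$components)
  models <- vector("list", n_t)
  centers <- array(NA_real_, dim = c(n_t, K, 3))
  intensity <- matrix(NA_real_, n_t, K)
  ch_int <- NULL
  if (!is.null(channels)) {
    for (nm in names(channels))
      if (length(channels[[nm]]) != n_t)
        stop("channel '", nm, "' has ", length(channels[[nm]]),
             " frames; expected ", n_t)
    ch_int <- lapply(channels, function(ch) matrix(NA_real_, n_t, K))
  }
  flagged <- vector("list", n_t)
  cur <- init
  for (t in seq_len(n_t)) {
    if (t > 1) {
      d_cur <- dim(frames[[t]]$data)
      if (!identical(d_cur, dim(frames[[t - 1]]$data)))
        stop("frame ", t, " shape mismatch: got ",
             paste(d_cur, collapse = "x"))
      cur <- track_frame(cur, frames[[t]], opts, v_prev = frames[[t - 1]])
    }
    models[[t]] <- cur
    flagged[[t]] <- attr(cur, "flagged")
    centers[t, , ] <- component_centers(cur)
    intensity[t, ] <- component_intensities(cur)
    if (!is.null(channels))
      for (nm in names(channels))
        ch_int[[nm]][t, ] <- estimate_channel_scalings(
          channels[[nm]][[t]], cur, opts$fit$support_radius)
  }
  structure(list(models = models, centers = centers, intensity = intensity,
                 channel_intensity = ch_int, flagged = flagged),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d components\n",
              dim(x$centers)[1], dim(x$centers)[2]))
  invisible(x)
}

#' Export a trajectory as long-format CSV
#'
#' One row per (frame, component): centre coordinates and the peak intensity
#' in the detection channel and every measured channel.
#'
#' @param traj a \code{trajectory}.
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_trajectory_csv <- function(traj, path) {
  n_t <- dim(traj$centers)[1]
  K <- dim(traj$centers)[2]
  df <- data.frame(frame = rep(seq_len(n_t), each = K),
                   component = rep(seq_len(K), times = n_t))
  df$mu1 <- as.vector(t(traj$centers[, , 1]))
  df$mu2 <- as.vector(t(traj$centers[, , 2]))
  df$mu3 <- as.vector(t(traj$centers[, , 3]))
  df$pi <- as.vector(t(traj$intensity))
  for (nm in names(traj$channel_intensity))
    df[[paste0("pi_", nm)]] <- as.vector(t(traj$channel_intensity[[nm]]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-component ratio trace between two measured channels
#'
#' The classic ratiometric activity readout (e.g. YFP/CFP of a FRET-based
#' calcium indicator).
#'
#' @param traj a \code{trajectory} tracked with both channels attached.
#' @param numerator,denominator channel names in
#'   \code{traj$channel_intensity}.
#' @return Matrix frames x components of intensity ratios.
#' @export
ratio_trace <- function(traj, numerator, denominator) {
  num <- traj$channel_intensity[[numerator]]
  den <- traj$channel_intensity[[denominator]]
  if (is.null(num) || is.null(den))
    stop("channel not found in trajectory")
  num / pmax(den, .Machine$double.eps)
}
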