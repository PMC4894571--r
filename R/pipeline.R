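#' Full parameter surface of the detection/tracking pipeline
#'
#' A single nested list collecting every tunable of Steps 1-4 plus the
#' tracking and evaluation options, with the package defaults filled in.
#' Configurations round-trip through YAML ([load_config()]) so a run is
#' reproducible from its config capture alone.
#'
#' @param ... named overrides of the defaults; nested lists are merged
#'   field-by-field.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preprocess = list(median_radius = 1, background_radius = 50,
                      blur_sigma = c(1, 1, 1)),
    threshold = list(method = "triangle", fixed_threshold = 0),
    peaks = list(radius = 3),
    clean = list(min_voxels = 27, region_threshold = "none"),
    curvature = list(grad_epsilon = NULL, kappa_threshold = 0),
    split = list(count_threshold = 10, border_margin = 1,
                 connectivity = 26, seed_merge_um = 1.0,
                 seed_min_depth_um = 0.2, prominence_um = 0.05),
    fit = list(max_iter = 30, rel_tol = 1e-5, merge_cutoff = 1.4,
               support_radius = 4, sigma_floor = 0.3, sigma_ceiling = 3.0,
               refine_maxit = 10, default_half_radius = 1.10),
    track = list(register = TRUE, upsample = 10, max_step_um = 3,
                 freeze = "all", max_iter = 8),
    seed = 1L)
  over <- list(...)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_cfg(cfg, over), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#' @param path config file; fields override the package defaults.
#' @return A \code{pipeline_config}.
#' @export
load_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::fromJSON(path)
  else yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Save a pipeline configuration as YAML
#' @param cfg a \code{pipeline_config}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

cfg_fit_options <- function(cfg, freeze = "none") {
  f <- cfg$fit
  fit_options(max_iter = f$max_iter, rel_tol = f$rel_tol,
              merge_cutoff = f$merge_cutoff,
              default_sigma = diag(f$default_half_radius^2, 3),
              support_radius = f$support_radius,
              sigma_floor = f$sigma_floor, sigma_ceiling = f$sigma_ceiling,
              refine_maxit = f$refine_maxit, freeze = freeze)
}

#' Run the full detection pipeline (Steps 1-4) on one volume
#'
#' Preprocess (denoise, background-subtract, blur), threshold, detect peaks
#' and run the seeded watershed, clean regions, compute iso-surface
#' curvatures, flag and split under-segmented regions, then fit the Gaussian
#' mixture and merge over-segmented components.
#'
#' @param v a \code{volume_image} (or a TIFF path readable by
#'   [read_volume_tiff()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the label volume (TIFF),
#'   mixture (CSV + JSON), seeds (CSV) and a run log (JSON) are written.
#' @param verbose print per-step object counts.
#' @return List with \code{mixture} (fitted \code{mixture_model}),
#'   \code{labels} (post-split \code{label_volume}), \code{preprocessed},
#'   and \code{log} (per-step counts).
#' @export
run_detect <- function(v, config = pipeline_config(), out_dir = NULL,
                       verbose = FALSE) {
  if (is.character(v)) v <- read_volume_tiff(v)
  stopifnot(is_volume_image(v))
  say <- function(...) if (verbose) message(sprintf(...))
  d <- dim(v$data)
  two_d <- d[3] == 1

  pp <- preprocess_params(
    median_radius = config$preprocess$median_radius,
    background_radius = config$preprocess$background_radius,
    blur_sigma = if (two_d) c(config$preprocess$blur_sigma[1:2], 0)
    else config$preprocess$blur_sigma)
  vp <- preprocess_volume(v, pp)
  mask <- global_threshold(vp, config$threshold$method,
                           config$threshold$fixed_threshold)
  say("threshold %.4g keeps %.1f%% of voxels", attr(mask, "threshold"),
      100 * mean(mask))

  seeds <- detect_peaks(vp, config$peaks$radius, mask)
  say("%d local peaks", nrow(seeds))
  if (!nrow(seeds))
    return(list(mixture = mixture_model(list()),
                labels = label_volume(array(0L, d), v$voxel_size),
                preprocessed = vp,
                log = list(peaks = 0, regions = 0, flagged = 0,
                           components = 0, merged = FALSE)))
  lv <- seeded_watershed(vp, seeds, mask, config$split$connectivity)
  lv <- clean_regions(lv, vp, config$clean$min_voxels,
                      config$clean$region_threshold)
  say("%d regions after cleaning", n_regions(lv))

  cf <- principal_curvatures(vp, config$curvature$grad_epsilon)
  neg <- negative_mask(cf, config$curvature$kappa_threshold)
  sp <- split_params(config$split$count_threshold,
                     config$split$border_margin,
                     config$split$connectivity,
                     config$split$seed_merge_um,
                     config$split$seed_min_depth_um,
                     config$split$prominence_um)
  spl <- split_undersegmented(lv, neg, sp)
  say("%d regions flagged as under-segmented, %d regions added",
      length(spl$flagged), spl$n_added)

  fo <- cfg_fit_options(config)
  init <- initialize_mixture(spl$labels, vp, fo)
  fitted <- fit_mixture(vp, init, fo)
  mg <- merge_close_components(fitted, vp, fo)
  say("%d components after fitting (%smerged)",
      length(mg$model$components), if (mg$merged) "" else "none ")

  log <- list(peaks = nrow(seeds), regions = n_regions(lv),
              flagged = length(spl$flagged), split_added = spl$n_added,
              components = length(mg$model$components),
              merged = mg$merged, threshold = attr(mask, "threshold"),
              fit_sse = mg$model$fit_sse)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_volume_tiff(spl$labels, file.path(out_dir, "labels.tif"))
    write_mixture_csv(mg$model, file.path(out_dir, "mixture.csv"))
    write_mixture_json(mg$model, file.path(out_dir, "mixture.json"))
    utils::write.csv(as.data.frame(seeds), file.path(out_dir, "seeds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(c(log, list(config = unclass(config))),
                         file.path(out_dir, "detect_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(mixture = mg$model, labels = spl$labels, preprocessed = vp,
       log = log)
}

#' Run tracking over a time series
#'
#' Detects on the first frame (unless an initial mixture is supplied), then
#' propagates the mixture with [track_series()], estimating per-channel
#' intensities at every frame.
#'
#' @param frames list of detection-channel \code{volume_image}, one per time
#'   point.
#' @param config a [pipeline_config()].
#' @param init optional initial \code{mixture_model} for frame 1; when
#'   missing, [run_detect()] runs on frame 1.
#' @param channels optional named list of per-channel frame lists (see
#'   [track_series()]).
#' @param out_dir optional output directory for the trajectory CSV.
#' @param preprocess logical; preprocess every frame before fitting.
#' @return The \code{trajectory} (with the frame-1 detection in attribute
#'   \code{"detection"} when it was computed here).
#' @export
run_track <- function(frames, config = pipeline_config(), init = NULL,
                      channels = NULL, out_dir = NULL, preprocess = TRUE) {
  stopifnot(length(frames) >= 1)
  det <- NULL
  if (preprocess) {
    pp <- preprocess_params(
      median_radius = config$preprocess$median_radius,
      background_radius = config$preprocess$background_radius,
      blur_sigma = config$preprocess$blur_sigma)
    frames <- lapply(frames, preprocess_volume, p = pp)
  }
  if (is.null(init)) {
    cfg1 <- config
    if (preprocess)  # frames are already preprocessed above
      cfg1$preprocess <- list(median_radius = 0, background_radius = 0,
                              blur_sigma = c(0, 0, 0))
    det <- run_detect(frames[[1]], cfg1)
    init <- det$mixture
  }
  topts <- track_options(
    fit = cfg_fit_options(config, freeze = config$track$freeze),
    register = config$track$register, upsample = config$track$upsample,
    max_step_um = config$track$max_step_um)
  topts$fit$max_iter <- config$track$max_iter
  traj <- track_series(frames, init, topts, channels = channels)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
  }
  if (!is.null(det)) attr(traj, "detection") <- det
  traj
}

#' Evaluate detections against ground truth
#'
#' @param detected matrix of detected centres, a \code{mixture_model}, or a
#'   CSV path in the [write_mixture_csv()] format.
#' @param truth matrix of true centres, a \code{ground_truth}, or a CSV path
#'   in the [write_truth_csv()] format.
#' @param out_path optional JSON report path.
#' @return List with the \code{match_report} and the performance
#'   \code{indices}.
#' @export
run_eval <- function(detected, truth, out_path = NULL) {
  pts <- function(x) {
    if (is.character(x)) x <- mixture_model(read_truth_csv(x))
    if (inherits(x, c("mixture_model", "ground_truth")))
      x <- component_centers(x)
    as_point_matrix(x)
  }
  tr <- pts(truth)
  if (!nrow(tr)) stop("empty ground truth")
  rep <- match_points(pts(detected), tr)
  idx <- compute_indices(rep)
  if (!is.null(out_path)) write_metric_report(idx, out_path)
  list(report = rep, indices = idx)
}
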