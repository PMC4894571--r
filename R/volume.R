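#' Scalar intensity volume with physical voxel sizes
#'
#' The universal carrier of the pipeline: a 2D or 3D grid of fluorescence
#' intensities together with the per-axis voxel size in micrometres. 2D
#' images are stored with a third extent of 1 so that every operation runs
#' through the same code path. The physical coordinate of voxel
#' \code{(i, j, k)} is \code{origin + (c(i, j, k) - 1) * voxel_size}.
#'
#' @param data numeric array (2D matrix or 3D array) of finite intensities.
#' @param voxel_size positive numeric vector of length 3 (or 2 for a 2D
#'   image), voxel edge lengths in micrometres along x1, x2, x3.
#' @param origin physical position (micrometres) of the first voxel, length 3.
#' @param channel_id,time_index optional integers identifying the channel and
#'   time point the volume was taken from.
#' @return An object of class \code{volume_image}.
#' @export
volume_image <- function(data, voxel_size, origin = c(0, 0, 0),
                         channel_id = NULL, time_index = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("`data` must be a 2D matrix or 3D array")
  if (length(voxel_size) == 2L) voxel_size <- c(voxel_size, 1)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive finite values")
  if (any(!is.finite(data))) stop("intensities must be finite")
  structure(
    list(data = data, voxel_size = voxel_size, origin = as.numeric(origin),
         channel_id = channel_id, time_index = time_index),
    class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, voxel size (%.3g, %.3g, %.3g) um\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

is_volume_image <- function(x) inherits(x, "volume_image")

#' Physical coordinates of the voxel grid
#'
#' @param v a \code{volume_image}.
#' @return List of three numeric vectors: the x1, x2, x3 coordinates (um) of
#'   the voxel centres along each axis.
#' @export
voxel_axes <- function(v) {
  d <- dim(v$data)
  lapply(1:3, function(a) v$origin[a] + (seq_len(d[a]) - 1) * v$voxel_size[a])
}

#' Integer-labeled segmentation aligned to a volume
#'
#' @param labels integer array, 0 = background, positive values = regions.
#' @param voxel_size,origin geometry, as in [volume_image()].
#' @return An object of class \code{label_volume}.
#' @export
label_volume <- function(labels, voxel_size, origin = c(0, 0, 0)) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be nonnegative")
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d regions\n",
              d[1], d[2], d[3], max(x$labels)))
  invisible(x)
}

#' Number of regions in a label volume
#' @param lv a \code{label_volume}.
#' @return Integer count of distinct positive labels.
#' @export
n_regions <- function(lv) length(setdiff(unique(as.vector(lv$labels)), 0L))

#' Read a multi-page TIFF as a volume
#'
#' Pages are stacked along x3. Volumes written by [write_volume_tiff()] are
#' accompanied by a JSON sidecar (\code{<path>.json}) holding the voxel size,
#' origin and the intensity scale used to fit the data into the float TIFF
#' range; when present it is restored transparently. For foreign TIFFs the
#' voxel size must be supplied.
#'
#' @param path TIFF file path.
#' @param voxel_size voxel size override (um); required if the file carries
#'   no description tag.
#' @return A \code{volume_image}.
#' @export
read_volume_tiff <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("TIFF file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!length(pages)) stop("no pages in TIFF: ", path)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
  dims <- dim(pages[[1]])
  for (p in seq_along(pages))
    if (!identical(dim(pages[[p]])[1:2], dims[1:2]))
      stop("TIFF page ", p, " of ", path, " has inconsistent size")
  # tiff gives row x col = x2 x x1; transpose to x1 x x2
  arr <- array(0, dim = c(dims[2], dims[1], length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- t(pages[[p]])
  scale <- 1
  offset <- 0
  origin <- c(0, 0, 0)
  if (!is.null(meta)) {
    if (!is.null(meta$intensity_scale)) scale <- meta$intensity_scale
    if (!is.null(meta$intensity_offset)) offset <- meta$intensity_offset
    if (is.null(voxel_size) && !is.null(meta$voxel_size))
      voxel_size <- meta$voxel_size
    if (!is.null(meta$origin)) origin <- meta$origin
  }
  if (is.null(voxel_size))
    stop("voxel_size not found in TIFF metadata; pass it explicitly")
  volume_image(arr * scale + offset, voxel_size, origin = origin)
}

#' Write a volume as a multi-page float TIFF
#'
#' One page per x3 plane. Intensities are scaled into [0, 1] for storage;
#' the scale, voxel size and origin are recorded in a JSON sidecar file
#' (\code{<path>.json}) so that [read_volume_tiff()] restores physical units
#' exactly.
#'
#' @param v a \code{volume_image} or \code{label_volume}.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_volume_tiff <- function(v, path) {
  if (inherits(v, "label_volume"))
    v <- volume_image(v$labels + 0, v$voxel_size, origin = v$origin)
  stopifnot(is_volume_image(v))
  lo <- min(v$data)
  scale <- max(max(v$data) - lo, 1e-12)
  jsonlite::write_json(
    list(voxel_size = v$voxel_size, origin = v$origin,
         intensity_scale = scale, intensity_offset = lo),
    paste0(path, ".json"), digits = NA)
  pages <- lapply(seq_len(dim(v$data)[3]),
                  function(k) pmin(pmax(t(v$data[, , k] - lo) / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}
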