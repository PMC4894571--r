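#' Match detected points to ground truth by mutual nearest neighbours
#'
#' A detected point and a ground-truth point form a true positive only if
#' each is the other's nearest neighbour (Euclidean distance, um). Truth
#' points without a mutual partner are false negatives; detected points
#' without one are false positives. Distance ties are broken by the lowest
#' index, making the matching deterministic.
#'
#' @param detected numeric matrix (n x 3) of detected centres, um.
#' @param truth numeric matrix (m x 3) of ground-truth centres, um.
#' @return An object of class \code{match_report}: list with counts
#'   \code{TP}, \code{FP}, \code{FN}, \code{GT} and a data frame
#'   \code{pairs} (detected index, truth index, distance um).
#' @export
match_points <- function(detected, truth) {
  detected <- as_point_matrix(detected)
  truth <- as_point_matrix(truth)
  n <- nrow(detected); m <- nrow(truth)
  pairs <- data.frame(detected = integer(0), truth = integer(0),
                      distance = numeric(0))
  if (n > 0 && m > 0) {
    D2 <- outer(rowSums(detected^2), rep(1, m)) +
      outer(rep(1, n), rowSums(truth^2)) - 2 * detected %*% t(truth)
    D <- sqrt(pmax(D2, 0))  # guard tiny negative round-off
    nn_of_det <- apply(D, 1, which.min)   # ties -> lowest index
    nn_of_tru <- apply(D, 2, which.min)
    mutual <- which(nn_of_tru[nn_of_det] == seq_len(n))
    det_idx <- mutual
    tru_idx <- nn_of_det[mutual]
    pairs <- data.frame(detected = det_idx, truth = tru_idx,
                        distance = D[cbind(det_idx, tru_idx)])
  }
  TP <- nrow(pairs)
  structure(list(TP = TP, FP = n - TP, FN = m - TP, GT = m, pairs = pairs),
            class = "match_report")
}

as_point_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("mu1", "mu2", "mu3")])
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  x <- as.matrix(x)
  if (nrow(x) && any(!is.finite(x))) stop("coordinates must be finite")
  x
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> GT=%g TP=%g FP=%g FN=%g\n",
              x$GT, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Detection performance indices
#'
#' From the matched counts: true/false positive and false negative rates
#' (each divided by the ground-truth count GT = TP + FN), the F-measure
#' \code{2 TP / (2 TP + FN + FP)} and the accuracy (Jaccard-style)
#' \code{TP / (TP + FN + FP)}. Non-integer counts are accepted so that
#' across-animal mean counts can be fed through the same arithmetic.
#'
#' @param r a \code{match_report}, or a list/vector with elements \code{TP},
#'   \code{FP}, \code{FN}.
#' @return List with \code{tp_rate}, \code{fp_rate}, \code{fn_rate},
#'   \code{f_measure}, \code{accuracy} and \code{GT}.
#' @export
compute_indices <- function(r) {
  TP <- r[["TP"]]; FP <- r[["FP"]]; FN <- r[["FN"]]
  stopifnot(is.numeric(TP), is.numeric(FP), is.numeric(FN),
            TP >= 0, FP >= 0, FN >= 0)
  GT <- TP + FN
  if (GT <= 0) stop("rates are undefined when GT = TP + FN is zero")
  list(tp_rate = TP / GT,
       fp_rate = FP / GT,
       fn_rate = FN / GT,
       f_measure = 2 * TP / (2 * TP + FN + FP),
       accuracy = TP / (TP + FN + FP),
       GT = GT)
}

#' Write a metric report as JSON
#' @param indices output of [compute_indices()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_metric_report <- function(indices, path) {
  jsonlite::write_json(indices, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
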