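# Binary clustering of the likelihood image into filament / non-filament.

#' Estimate foreground by two-class clustering of likelihood values
#'
#' Partitions pixels into two clusters by 1-D two-means clustering of the
#' likelihood values (centroids initialized at the minimum and maximum value,
#' Lloyd iterations to convergence; foreground is the cluster with the larger
#' centroid, equivalently a threshold at the midpoint of the converged
#' centroids). Connected foreground components (8-connectivity) smaller than
#' `min_object_px` pixels are then removed.
#'
#' @param lik likelihood values: a matrix or an [enhance()] result.
#' @param min_object_px minimum surviving component size in pixels.
#' @return list of class `foreground_mask` with `mask` (0/1 integer matrix),
#'   `threshold` (the equivalent scalar threshold) and `min_object_px`.
#' @export
estimate_foreground <- function(lik, min_object_px = 20L) {
  v <- if (inherits(lik, "likelihood")) lik$values else lik
  stopifnot(is.matrix(v), min_object_px >= 1)
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) {
    warning("degenerate likelihood image (all values equal); returning all-background mask")
    return(structure(list(mask = matrix(0L, nrow(v), ncol(v)),
                          threshold = Inf,
                          min_object_px = as.integer(min_object_px)),
                     class = "foreground_mask"))
  }
  thr <- two_means_threshold(as.vector(v))
  mask <- matrix(as.integer(v >= thr), nrow(v), ncol(v))
  mask <- remove_small_components(mask, min_object_px)
  structure(list(mask = mask, threshold = thr,
                 min_object_px = as.integer(min_object_px)),
            class = "foreground_mask")
}

# 1-D two-means: centroids start at min and max, Lloyd iterations until the
# class boundary stops moving; returns the midpoint of the final centroids.
two_means_threshold <- function(v, max_iter = 100L) {
  c1 <- min(v); c2 <- max(v)
  thr <- (c1 + c2) / 2
  for (i in seq_len(max_iter)) {
    lo <- v < thr
    if (!any(lo) || all(lo)) break
    c1 <- mean(v[lo]); c2 <- mean(v[!lo])
    new_thr <- (c1 + c2) / 2
    if (abs(new_thr - thr) < 1e-12) { thr <- new_thr; break }
    thr <- new_thr
  }
  thr
}

# Drop 8-connected foreground components below min_px pixels.
remove_small_components <- function(mask, min_px) {
  lab <- label8(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= min_px
  out <- matrix(0L, nrow(mask), ncol(mask))
  sel <- lab > 0L
  out[sel] <- as.integer(keep[lab[sel]])
  out
}

#' Label 8-connected components of a binary matrix
#'
#' @param mask 0/1 matrix (logical or integer).
#' @return integer matrix of component labels, 0 for background.
#' @export
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  .label8_cpp(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
}
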