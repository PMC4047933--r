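# Filament length distribution and between-group comparison.

#' Summarize filament lengths into a distribution
#'
#' Discards paths shorter than `min_length`, histograms the remaining
#' lengths over `[0, max]`, and computes the weighted average length: the
#' mean of per-image mean lengths weighted by per-image filament count
#' (equivalently the pooled mean over all filaments), with a standard error
#' propagated from the per-image variances.
#'
#' @param paths a [disambiguate()] result, or a numeric vector of lengths.
#' @param bin_width histogram bin width (default 0.5 um when `pixel_size_um`
#'   is given, else 5 px).
#' @param min_length shortest length kept (same unit as `paths` lengths in
#'   px; default 3 px, dropping thinning artifacts).
#' @param image_ids optional per-path image identifier for multi-image
#'   pooling; default treats all paths as one image.
#' @param pixel_size_um optional physical pixel size; lengths are converted
#'   to micrometres after the `min_length` filter.
#' @return object of class `length_distribution`: `lengths`, `bin_edges`,
#'   `counts`, `weighted_mean`, `weighted_mean_se`, `per_image` (data.frame
#'   with `image`, `n`, `mean`, `var`), `unit`.
#' @export
#' @examples
#' d <- length_distribution(c(2, 2, 2, 5), image_ids = c(1, 1, 1, 2))
#' d$weighted_mean  # (3 * 2 + 1 * 5) / 4
length_distribution <- function(paths, bin_width = NULL, min_length = 3,
                                image_ids = NULL, pixel_size_um = NULL) {
  lengths <- if (is.numeric(paths)) as.numeric(paths)
             else vapply(paths, function(p) p$length_px, 1)
  if (is.null(image_ids)) image_ids <- rep(1L, length(lengths))
  stopifnot(length(image_ids) == length(lengths))
  keep <- lengths >= min_length
  lengths <- lengths[keep]
  image_ids <- image_ids[keep]
  unit <- "px"
  if (!is.null(pixel_size_um)) {
    lengths <- lengths * pixel_size_um
    unit <- "um"
  }
  if (is.null(bin_width)) bin_width <- if (unit == "um") 0.5 else 5
  stopifnot(bin_width > 0)

  if (length(lengths) == 0) {
    return(structure(list(lengths = numeric(0), bin_edges = numeric(0),
                          counts = integer(0), weighted_mean = NA_real_,
                          weighted_mean_se = NA_real_,
                          per_image = data.frame(image = character(0),
                                                 n = integer(0), mean = numeric(0),
                                                 var = numeric(0)),
                          unit = unit),
                     class = "length_distribution"))
  }

  edges <- seq(0, ceiling(max(lengths) / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 2) edges <- c(0, bin_width)
  counts <- as.integer(table(cut(lengths, edges, include.lowest = TRUE,
                                 right = TRUE)))

  ids <- factor(image_ids)
  n_i <- as.integer(tapply(lengths, ids, length))
  m_i <- as.numeric(tapply(lengths, ids, mean))
  v_i <- as.numeric(tapply(lengths, ids, function(x)
    if (length(x) >= 2) var(x) else 0))
  N <- sum(n_i)
  wmean <- sum(n_i * m_i) / N
  wse <- sqrt(sum(n_i^2 * (v_i / pmax(n_i, 1))) / N^2)

  structure(list(lengths = lengths, bin_edges = edges, counts = counts,
                 weighted_mean = wmean, weighted_mean_se = wse,
                 per_image = data.frame(image = levels(ids), n = n_i,
                                        mean = m_i, var = v_i),
                 unit = unit),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("length_distribution: %d filaments over %d image(s)\n",
              length(x$lengths), nrow(x$per_image)))
  if (is.na(x$weighted_mean)) {
    cat("weighted mean length: undefined (no filaments)\n")
  } else {
    cat(sprintf("weighted mean length: %.2f +/- %.2f %s\n",
                x$weighted_mean, x$weighted_mean_se, x$unit))
  }
  invisible(x)
}

#' Compare the filament lengths of two groups of images
#'
#' Two-sample unequal-variance (Welch) t-test on the per-image mean filament
#' lengths of the two distributions.
#'
#' @param a,b [length_distribution()] objects, each built from at least two
#'   images.
#' @return two-sided p-value.
#' @export
compare_groups <- function(a, b) {
  stopifnot(inherits(a, "length_distribution"),
            inherits(b, "length_distribution"))
  if (nrow(a$per_image) < 2 || nrow(b$per_image) < 2)
    stop("each group needs per-image means from at least 2 images", call. = FALSE)
  t.test(a$per_image$mean, b$per_image$mean, var.equal = FALSE)$p.value
}
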