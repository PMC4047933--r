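# Bank of artificial curvilinear filament templates (rotation x scale x
# curvature), used to score how filament-like each pixel neighbourhood is.

#' Build a bank of artificial filament templates
#'
#' Each template is a constant-curvature arc ridge with Gaussian
#' cross-section, rendered on the smallest odd-sized square grid containing
#' the arc plus 3 sigma padding, then mean-subtracted and scaled to unit
#' Euclidean norm. Rotations are equally spaced over `[0, pi)` (ridges are
#' symmetric under reversal, so a half-turn suffices); curvatures should
#' include signed pairs because only half the rotation circle is enumerated.
#'
#' @param lengths_px arc lengths of the templates (px).
#' @param width_sigmas_px Gaussian cross-section SDs (px).
#' @param n_rotations number of equally spaced rotations over `[0, pi)`.
#' @param curvatures_per_px signed curvatures (1/px); each must satisfy
#'   `|curvature| * length < pi` (less than a half circle).
#' @return object of class `template_bank`: list with `kernels` (list of
#'   matrices) and `params` (data.frame with `length_px`, `width_sigma_px`,
#'   `curvature_per_px`, `rotation_rad` per kernel).
#' @export
#' @examples
#' bank <- template_bank(lengths_px = 15, width_sigmas_px = 1.5,
#'                       n_rotations = 4, curvatures_per_px = 0)
#' length(bank$kernels)
template_bank <- function(lengths_px = c(15, 25),
                          width_sigmas_px = c(1.5, 2.5),
                          n_rotations = 12L,
                          curvatures_per_px = c(0, 0.01, -0.01, 0.02, -0.02)) {
  stopifnot(n_rotations >= 1, all(lengths_px > 0), all(width_sigmas_px > 0))
  for (L in lengths_px)
    for (k in curvatures_per_px)
      if (abs(k) * L >= pi)
        stop("template arc must subtend less than a half circle: |curvature| * length < pi",
             call. = FALSE)
  rotations <- seq(0, pi, length.out = n_rotations + 1L)[seq_len(n_rotations)]
  params <- expand.grid(length_px = lengths_px,
                        width_sigma_px = width_sigmas_px,
                        curvature_per_px = curvatures_per_px,
                        rotation_rad = rotations,
                        KEEP.OUT.ATTRS = FALSE)
  kernels <- lapply(seq_len(nrow(params)), function(i)
    render_template(params$length_px[i], params$width_sigma_px[i],
                    params$curvature_per_px[i], params$rotation_rad[i]))
  structure(list(kernels = kernels, params = params), class = "template_bank")
}

# Render one zero-mean, unit-norm template kernel.
render_template <- function(length_px, width_sigma_px, curvature_per_px,
                            rotation_rad) {
  poly <- arc_polyline(0, 0, rotation_rad, curvature_per_px, length_px,
                       step = 0.5)
  ext <- max(abs(poly)) + 3 * width_sigma_px
  half <- ceiling(ext)
  size <- 2L * half + 1L
  ctr <- half + 1L
  poly[, 1] <- poly[, 1] + ctr
  poly[, 2] <- poly[, 2] + ctr
  grid <- cbind(rep(seq_len(size), times = size),
                rep(seq_len(size), each = size))
  d <- dist_to_polyline(grid, poly)
  k <- matrix(exp(-d^2 / (2 * width_sigma_px^2)), size, size)
  k <- k - mean(k)
  k / sqrt(sum(k^2))
}

#' @export
print.template_bank <- function(x, ...) {
  p <- x$params
  cat(sprintf("template_bank: %d kernels (%d lengths x %d widths x %d curvatures x %d rotations)\n",
              length(x$kernels), length(unique(p$length_px)),
              length(unique(p$width_sigma_px)),
              length(unique(p$curvature_per_px)),
              length(unique(p$rotation_rad))))
  cat(sprintf("kernel sizes: %s px\n",
              paste(sort(unique(vapply(x$kernels, nrow, 1L))), collapse = ", ")))
  invisible(x)
}

#' Write the template kernels to a multi-page TIFF for inspection
#'
#' @param bank a [template_bank()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_bank_tiff <- function(bank, path) {
  size <- max(vapply(bank$kernels, nrow, 1L))
  pages <- lapply(bank$kernels, function(k) {
    out <- matrix(0, size, size)
    off <- (size - nrow(k)) %/% 2
    out[off + seq_len(nrow(k)), off + seq_len(ncol(k))] <- k
    rng <- range(out)
    (out - rng[1]) / max(rng[2] - rng[1], 1e-12)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
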