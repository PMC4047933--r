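# Filament-likelihood (enhanced) image: best template response combined
# with the original intensity.

#' Best template-bank response at every pixel
#'
#' Cross-correlates the image with every kernel in the bank (zero-padded
#' boundaries, FFT-based) and keeps, per pixel, the maximum response over
#' kernels, clamped below at zero, together with the winning kernel's
#' rotation and index (ties broken by the lowest kernel index). Because every
#' kernel has zero mean, the response is invariant to constant offsets in the
#' image, which makes an explicit local mean subtraction unnecessary.
#'
#' @param image numeric matrix of nonnegative intensities.
#' @param bank a [template_bank()].
#' @return list with `response` (matrix, >= 0), `best_rotation_rad` (matrix),
#'   `best_template_index` (integer matrix), `valid` (logical matrix marking
#'   pixels farther than half the largest kernel from the border).
#' @export
best_response <- function(image, bank) {
  stopifnot(is.matrix(image), length(bank$kernels) >= 1)
  if (any(!is.finite(image)) || any(image < 0))
    stop("image values must be finite and nonnegative", call. = FALSE)
  sizes <- vapply(bank$kernels, nrow, 1L)
  if (nrow(image) < min(sizes) || ncol(image) < min(sizes))
    stop("image is smaller than every kernel in the bank", call. = FALSE)
  response <- matrix(-Inf, nrow(image), ncol(image))
  best_idx <- matrix(1L, nrow(image), ncol(image))
  for (i in seq_along(bank$kernels)) {
    k <- bank$kernels[[i]]
    if (nrow(k) > nrow(image) || ncol(k) > ncol(image)) next
    # filter2 convolves; flip the kernel to obtain correlation
    kf <- k[rev(seq_len(nrow(k))), rev(seq_len(ncol(k))), drop = FALSE]
    r <- EBImage::filter2(image, kf, boundary = 0)
    upd <- r > response
    response[upd] <- r[upd]
    best_idx[upd] <- i
  }
  response[response < 0] <- 0
  half <- max(sizes) %/% 2
  valid <- matrix(FALSE, nrow(image), ncol(image))
  rr <- seq_len(nrow(image)) > half & seq_len(nrow(image)) <= nrow(image) - half
  cc <- seq_len(ncol(image)) > half & seq_len(ncol(image)) <= ncol(image) - half
  valid[rr, cc] <- TRUE
  list(response = response,
       best_rotation_rad = matrix(bank$params$rotation_rad[best_idx],
                                  nrow(image), ncol(image)),
       best_template_index = best_idx,
       valid = valid)
}

#' Combine template response and intensity into a likelihood image
#'
#' Min-max-normalizes the response map and the original intensity separately
#' and multiplies them pixelwise, so a pixel scores high only when it both
#' looks like a ridge and is bright. This suppresses diffuse background
#' fluorescence (bright but not ridge-like, e.g. unpolymerized actin) as well
#' as isolated noise spikes. A map with zero range normalizes to all zeros.
#'
#' @param response nonnegative response matrix (from [best_response()]).
#' @param image the original intensity matrix, same shape.
#' @return matrix of values in `[0, 1]`.
#' @export
likelihood_image <- function(response, image) {
  if (!all(dim(response) == dim(image)))
    stop("response and image must have the same shape", call. = FALSE)
  minmax01(response) * minmax01(image)
}

minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Enhance an image with a template bank
#'
#' Convenience wrapper running [best_response()] then [likelihood_image()].
#'
#' @inheritParams best_response
#' @return list of class `likelihood` with `values` (likelihood in `[0, 1]`),
#'   `response`, `best_rotation_rad`, `best_template_index`, `valid`.
#' @export
#' @examples
#' net <- render_network(network_spec(n_filaments = 2, seed = 3))
#' bank <- template_bank(lengths_px = 15, width_sigmas_px = 1.5,
#'                       n_rotations = 6, curvatures_per_px = 0)
#' lik <- enhance(net$image, bank)
#' range(lik$values)
enhance <- function(image, bank) {
  br <- best_response(image, bank)
  structure(c(list(values = likelihood_image(br$response, image)), br),
            class = "likelihood")
}
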