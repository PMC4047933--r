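# Synthetic filament-network generator with ground truth.

#' Specify a synthetic filament-network image
#'
#' Describes one artificial fluorescence micrograph of a filament network:
#' filament lengths are Gaussian with a pre-defined mean and standard
#' deviation (truncated below at `min_length_px` by resampling), centerlines
#' are constant-curvature arcs with uniformly random midpoint, orientation
#' and signed curvature, each rendered as a ridge with Gaussian cross-section;
#' overlaps composite by pixelwise maximum, and additive Gaussian noise is
#' applied on top of a constant background.
#'
#' Defaults mirror the validation conditions used throughout the package:
#' 128 x 128 px images, length mean 50 px and SD 20 px.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param n_filaments number of filaments (>= 0).
#' @param length_mean_px,length_sd_px Gaussian length distribution (px).
#' @param min_length_px lower truncation for sampled lengths (px).
#' @param width_sigma_px SD of the Gaussian cross-section (px).
#' @param curvature_max_per_px curvature magnitude bound (1/px); per-filament
#'   curvature is uniform on `[-max, max]`.
#' @param foreground_peak ridge peak intensity above background.
#' @param background_level constant background intensity.
#' @param noise_sd SD of additive zero-mean Gaussian noise (default 10% of
#'   `foreground_peak`).
#' @param seed integer seed; identical specs give bit-identical images.
#' @return object of class `network_spec`.
#' @export
#' @examples
#' spec <- network_spec(n_filaments = 3, seed = 7)
#' net <- render_network(spec)
#' dim(net$image)
network_spec <- function(image_height_px = 128L, image_width_px = 128L,
                         n_filaments = 10L,
                         length_mean_px = 50, length_sd_px = 20,
                         min_length_px = 10, width_sigma_px = 1.5,
                         curvature_max_per_px = 0.01,
                         foreground_peak = 100, background_level = 10,
                         noise_sd = 0.1 * foreground_peak, seed = 1L) {
  spec <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    n_filaments = as.integer(n_filaments),
    length_mean_px = length_mean_px, length_sd_px = length_sd_px,
    min_length_px = min_length_px, width_sigma_px = width_sigma_px,
    curvature_max_per_px = curvature_max_per_px,
    foreground_peak = foreground_peak, background_level = background_level,
    noise_sd = noise_sd, seed = as.integer(seed))
  validate_network_spec(spec)
  structure(spec, class = "network_spec")
}

validate_network_spec <- function(spec) {
  with(spec, {
    if (image_height_px < 1 || image_width_px < 1)
      stop("image must have positive area", call. = FALSE)
    if (n_filaments < 0) stop("n_filaments must be >= 0", call. = FALSE)
    if (length_mean_px <= 0) stop("length_mean_px must be > 0", call. = FALSE)
    if (length_sd_px < 0) stop("length_sd_px must be >= 0", call. = FALSE)
    if (min_length_px <= 0) stop("min_length_px must be > 0", call. = FALSE)
    if (min_length_px > length_mean_px + 4 * length_sd_px)
      stop("min_length_px lies above the plausible length range", call. = FALSE)
    if (width_sigma_px <= 0) stop("width_sigma_px must be > 0", call. = FALSE)
    if (curvature_max_per_px < 0) stop("curvature_max_per_px must be >= 0", call. = FALSE)
    if (foreground_peak <= 0) stop("foreground_peak must be > 0", call. = FALSE)
    if (background_level < 0 || noise_sd < 0)
      stop("background_level and noise_sd must be >= 0", call. = FALSE)
  })
  invisible(spec)
}

#' Draw one ground-truth filament
#'
#' Samples a filament from the distribution described by `spec` using the
#' current RNG state: length from a truncated Gaussian, midpoint uniform over
#' the frame, orientation uniform on `[0, pi)`, constant signed curvature
#' uniform on `[-curvature_max, curvature_max]`. The arc is clipped at the
#' frame (the longest contiguous in-frame run is kept) and the recorded
#' `length_px` is the in-frame arc length.
#'
#' @param spec a [network_spec()].
#' @return list with `centerline` (matrix of (row, col)), `length_px`,
#'   `curvature_per_px`, `orientation_rad`.
#' @export
sample_filament <- function(spec) {
  validate_network_spec(spec)
  len <- rnorm(1, spec$length_mean_px, spec$length_sd_px)
  while (len < spec$min_length_px)
    len <- rnorm(1, spec$length_mean_px, spec$length_sd_px)
  r <- runif(1, 1, spec$image_height_px)
  c <- runif(1, 1, spec$image_width_px)
  theta <- runif(1, 0, pi)
  k <- if (spec$curvature_max_per_px > 0)
    runif(1, -spec$curvature_max_per_px, spec$curvature_max_per_px) else 0
  poly <- arc_polyline(r, c, theta, k, len, step = 0.5)
  poly <- clip_to_frame(poly, spec$image_height_px, spec$image_width_px)
  list(centerline = poly,
       length_px = polyline_length(poly),
       curvature_per_px = k,
       orientation_rad = theta %% pi)
}

# Keep the longest contiguous run of polyline vertices inside the physical
# image frame [0.5, H + 0.5] x [0.5, W + 0.5].
clip_to_frame <- function(poly, h, w) {
  inside <- poly[, 1] >= 0.5 & poly[, 1] <= h + 0.5 &
            poly[, 2] >= 0.5 & poly[, 2] <= w + 0.5
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[integer(0), , drop = FALSE])
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  best <- ok[which.max(r$lengths[ok])]
  poly[starts[best]:ends[best], , drop = FALSE]
}

#' Render a synthetic filament-network image with ground truth
#'
#' Draws `spec$n_filaments` filaments (see [sample_filament()]), renders each
#' centerline as a Gaussian-cross-section ridge of peak `foreground_peak`
#' (overlaps combined by pixelwise maximum), adds the constant background and
#' zero-mean Gaussian noise, and clips negative values at zero. All sampling
#' happens under `spec$seed`, so an identical spec reproduces the image and
#' ground truth exactly.
#'
#' Because overlapping ridges composite by maximum, a filament lying almost
#' on top of another would be invisible in the rendered image, and a
#' filament ending tangentially on another is indistinguishable from one
#' continuing across it — in either case the ground truth is unrecoverable
#' in principle. Placements are therefore rejected and redrawn when a
#' contact with an already-placed filament is locally tangential (closer
#' than 4 px with tangents within 30 degrees) or shadows it for 10 px or
#' more within 3 px; transversal crossings are unaffected, and position and
#' orientation remain uniform over the accepted configurations.
#'
#' @param spec a [network_spec()].
#' @return list of class `synthetic_network` with `image` (numeric matrix)
#'   and `truth` (list with `filaments`, `spec`).
#' @export
render_network <- function(spec) {
  validate_network_spec(spec)
  h <- spec$image_height_px; w <- spec$image_width_px
  withr::with_seed(spec$seed, {
    fils <- list()
    for (i in seq_len(spec$n_filaments)) {
      for (attempt in seq_len(200L)) {
        cand <- sample_filament(spec)
        if (is_resolvable(cand, fils)) break
      }
      fils[[i]] <- cand
    }
    canvas <- matrix(0, h, w)
    for (f in fils)
      if (nrow(f$centerline) >= 1)
        canvas <- add_ridge(canvas, f$centerline, spec$width_sigma_px,
                            spec$foreground_peak)
    img <- canvas + spec$background_level
    if (spec$noise_sd > 0)
      img <- img + matrix(rnorm(h * w, 0, spec$noise_sd), h, w)
    img[img < 0] <- 0
  })
  structure(list(image = img,
                 truth = list(filaments = fils, spec = spec)),
            class = "synthetic_network")
}

#' Generate a bank of validation images at increasing filament density
#'
#' Replicates the validation protocol: for each density level (filaments per
#' image) renders `images_per_level` independent networks. Per-image seeds
#' are derived deterministically from the master seed, so the whole bank is
#' reproducible from `(base_spec, density_levels, images_per_level, seed)`.
#'
#' @param base_spec a [network_spec()]; its `n_filaments` and `seed` are
#'   overridden per image.
#' @param density_levels integer vector of filaments-per-image levels.
#' @param images_per_level images per density level (>= 1).
#' @param seed master seed.
#' @return list of `synthetic_network` objects (length
#'   `length(density_levels) * images_per_level`), each annotated with
#'   `density_level` and `image_index`.
#' @export
validation_bank <- function(base_spec = network_spec(),
                            density_levels = c(5L, 10L, 15L, 20L),
                            images_per_level = 10L, seed = 1L) {
  stopifnot(length(density_levels) >= 1, images_per_level >= 1)
  out <- vector("list", length(density_levels) * images_per_level)
  idx <- 0L
  for (li in seq_along(density_levels)) {
    for (im in seq_len(images_per_level)) {
      idx <- idx + 1L
      spec_i <- base_spec
      spec_i$n_filaments <- as.integer(density_levels[li])
      spec_i$seed <- derive_seed(seed, li, im)
      net <- render_network(spec_i)
      net$density_level <- density_levels[li]
      net$image_index <- im
      out[[idx]] <- net
    }
  }
  out
}

# Local tangent of a polyline at vertex i (window of +/- 3 vertices).
polyline_tangent_at <- function(P, i) {
  n <- nrow(P)
  a <- max(1L, i - 3L); b <- min(n, i + 3L)
  v <- P[b, ] - P[a, ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) c(1, 0) else v / nv
}

# A candidate filament is resolvable against the already-placed network if
# every close approach (< 4 px) to an existing centerline is locally
# transversal (tangents differing by >= 30 degrees), and no contiguous
# >= 10 px stretch of its centerline shadows one existing centerline within
# 3 px. Tangential contacts -- near-parallel shadowing, collinear abutment,
# glancing crossings -- fuse into a single ridge under maximum compositing,
# or make "terminates here" vs "continues across" undecidable, so their
# ground truth could never be recovered from the rendered image.
is_resolvable <- function(cand, fils, shadow_dist_px = 3, shadow_run_px = 10,
                          contact_dist_px = 4, contact_angle_deg = 30) {
  if (length(fils) == 0 || nrow(cand$centerline) == 0) return(TRUE)
  Cc <- cand$centerline
  step <- if (nrow(Cc) >= 2) sqrt(sum((Cc[2, ] - Cc[1, ])^2)) else 0.5
  max_run_pts <- max(2L, ceiling(shadow_run_px / max(step, 1e-6)))
  cos_gate <- cos(contact_angle_deg * pi / 180)
  for (f in fils) {
    Cf <- f$centerline
    if (nrow(Cf) == 0) next
    d <- dist_to_polyline(Cc, Cf)
    close <- d <= shadow_dist_px
    if (any(close)) {
      r <- rle(close)
      if (any(r$lengths[r$values] >= max_run_pts)) return(FALSE)
    }
    contact <- which(d <= contact_dist_px)
    for (i in contact) {
      d2 <- (Cf[, 1] - Cc[i, 1])^2 + (Cf[, 2] - Cc[i, 2])^2
      j <- which.min(d2)
      tc <- polyline_tangent_at(Cc, i)
      tf <- polyline_tangent_at(Cf, j)
      if (abs(sum(tc * tf)) > cos_gate) return(FALSE)  # locally tangential
    }
    # endpoint rule with longer reach: an end lying near-collinear with the
    # other centerline (even across a small gap) reads as a continuation
    if (!transversal_ends(Cc, Cf, 2 * contact_dist_px, cos_gate)) return(FALSE)
    if (!transversal_ends(Cf, Cc, 2 * contact_dist_px, cos_gate)) return(FALSE)
  }
  TRUE
}

# TRUE unless an endpoint of A approaches curve B within `reach` px with
# locally aligned tangents.
transversal_ends <- function(A, B, reach, cos_gate) {
  n <- nrow(A)
  for (i in c(1L, n)) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2
    j <- which.min(d2)
    if (d2[j] > reach^2) next
    ta <- polyline_tangent_at(A, i)
    tb <- polyline_tangent_at(B, j)
    if (abs(sum(ta * tb)) > cos_gate) return(FALSE)
  }
  TRUE
}

# Deterministic per-image seed below 2^31, mixing master seed, level and
# image indices into well-separated streams.
derive_seed <- function(master, level_idx, image_idx) {
  m <- (as.numeric(master) * 2654435761) %% 2147483647
  as.integer((m + level_idx * 1299709 + image_idx * 7919) %% 2147483647)
}
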