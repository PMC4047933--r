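# Shared fixtures, built in code at test time.

# small template bank used where the full default bank would be overkill
tiny_bank_cache <- new.env()
tiny_bank <- function() {
  if (is.null(tiny_bank_cache$bank))
    tiny_bank_cache$bank <- template_bank(
      lengths_px = 15, width_sigmas_px = 1.5, n_rotations = 8,
      curvatures_per_px = c(0, 0.01, -0.01))
  tiny_bank_cache$bank
}

default_bank_cache <- new.env()
default_bank <- function() {
  if (is.null(default_bank_cache$bank))
    default_bank_cache$bank <- template_bank()
  default_bank_cache$bank
}

# random blob mask: thresholded smoothed noise, guaranteed nonempty
random_blob_mask <- function(seed, n = 48L) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * n), n, n)
    k <- matrix(1, 5, 5) / 25
    s <- EBImage::filter2(x, k, boundary = 0)
    m <- matrix(as.integer(s > quantile(s, 0.8)), n, n)
  })
  if (!any(m > 0)) m[n %/% 2, n %/% 2] <- 1L
  m
}

random_skeleton <- function(seed, n = 48L) {
  thin_mask(random_blob_mask(seed, n))
}

# digital straight line between two pixels (rounded parametric walk)
digital_line <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  t <- seq(0, 1, length.out = n)
  unique(cbind(round(r0 + t * (r1 - r0)), round(c0 + t * (c1 - c0))))
}

put_pixels <- function(mask, px) {
  mask[px] <- 1L
  mask
}

# noise-free rendering of one straight ridge with known geometry
render_straight <- function(theta, length_px = 60, sigma = 1.5, peak = 100,
                            bg = 10, size = 128L, mid = NULL) {
  if (is.null(mid)) mid <- c(size / 2, size / 2)
  poly <- filatrace:::arc_polyline(mid[1], mid[2], theta, 0, length_px, 0.5)
  canvas <- matrix(0, size, size)
  canvas <- filatrace:::add_ridge(canvas, poly, sigma, peak)
  list(image = canvas + bg, centerline = poly,
       length_px = filatrace:::polyline_length(poly))
}

# two straight ridges crossing at the image centre
render_crossing <- function(angle_deg, seed = 1, noise_sd = 10,
                            length_px = 60) {
  a <- render_straight(0.3, length_px)
  b <- render_straight(0.3 + angle_deg * pi / 180, length_px)
  img <- pmax(a$image, b$image)
  if (noise_sd > 0)
    withr::with_seed(seed,
      img <- pmax(img + matrix(rnorm(length(img), 0, noise_sd),
                               nrow(img), ncol(img)), 0))
  list(image = img,
       truth = list(filaments = list(
         list(centerline = a$centerline, length_px = a$length_px),
         list(centerline = b$centerline, length_px = b$length_px))))
}
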