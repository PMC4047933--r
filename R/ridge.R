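# Constant-curvature arc geometry and Gaussian ridge rendering.
# Shared by the synthetic-network generator and the template bank so that
# simulated filaments and matched templates live in the same shape family.

#' Sample a constant-curvature arc as a polyline
#'
#' Parametrizes an arc by its midpoint, the tangent orientation at the
#' midpoint, a signed curvature and a total arc length, and returns points
#' spaced `step` pixels apart along the arc (endpoints included).
#'
#' @param mid_row,mid_col midpoint coordinates (pixels).
#' @param orientation_rad tangent angle at the midpoint, measured from the
#'   column axis towards the row axis.
#' @param curvature_per_px signed curvature (1/pixels); 0 gives a segment.
#' @param length_px total arc length in pixels.
#' @param step spacing of returned points along the arc (pixels).
#' @return matrix with columns `row`, `col`; rows ordered along the arc.
#' @keywords internal
arc_polyline <- function(mid_row, mid_col, orientation_rad, curvature_per_px,
                         length_px, step = 0.5) {
  stopifnot(length_px > 0, step > 0)
  n <- max(2L, as.integer(ceiling(length_px / step)) + 1L)
  s <- seq(-length_px / 2, length_px / 2, length.out = n)
  u <- c(sin(orientation_rad), cos(orientation_rad))   # (drow, dcol)
  nv <- c(u[2], -u[1])                                 # unit normal
  k <- curvature_per_px
  if (abs(k) < 1e-12) {
    a <- s
    b <- rep(0, n)
  } else {
    a <- sin(k * s) / k
    b <- (1 - cos(k * s)) / k
  }
  cbind(row = mid_row + a * u[1] + b * nv[1],
        col = mid_col + a * u[2] + b * nv[2])
}

# Arc length of a polyline: sum of chord lengths.
polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Minimum distance from each query point to a polyline (point-to-segment,
# exact). `points` and `poly` are n x 2 / m x 2 matrices of (row, col).
dist_to_polyline <- function(points, poly) {
  np <- nrow(points)
  if (nrow(poly) == 1) {
    return(sqrt((points[, 1] - poly[1, 1])^2 + (points[, 2] - poly[1, 2])^2))
  }
  d2 <- rep(Inf, np)
  pr <- points[, 1]; pc <- points[, 2]
  for (i in seq_len(nrow(poly) - 1)) {
    ar <- poly[i, 1]; ac <- poly[i, 2]
    br <- poly[i + 1, 1]; bc <- poly[i + 1, 2]
    vr <- br - ar; vc <- bc - ac
    vv <- vr * vr + vc * vc
    if (vv < 1e-24) {
      dr <- pr - ar; dc <- pc - ac
      d2 <- pmin(d2, dr * dr + dc * dc)
      next
    }
    t <- ((pr - ar) * vr + (pc - ac) * vc) / vv
    t <- pmin(pmax(t, 0), 1)
    dr <- pr - (ar + t * vr)
    dc <- pc - (ac + t * vc)
    d2 <- pmin(d2, dr * dr + dc * dc)
  }
  sqrt(d2)
}

# Add a Gaussian-cross-section ridge along `poly` onto `canvas` (by pixelwise
# maximum, emulating fluorophore saturation where filaments overlap).
# Only pixels within 4 sigma of the polyline bounding box are touched.
add_ridge <- function(canvas, poly, width_sigma, peak) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  pad <- ceiling(4 * width_sigma)
  r0 <- max(1L, floor(min(poly[, 1])) - pad)
  r1 <- min(nr, ceiling(max(poly[, 1])) + pad)
  c0 <- max(1L, floor(min(poly[, 2])) - pad)
  c1 <- min(nc, ceiling(max(poly[, 2])) + pad)
  if (r0 > r1 || c0 > c1) return(canvas)
  rows <- r0:r1; cols <- c0:c1
  grid <- cbind(rep(rows, times = length(cols)),
                rep(cols, each = length(rows)))
  d <- dist_to_polyline(grid, poly)
  v <- peak * exp(-d^2 / (2 * width_sigma^2))
  sub <- canvas[rows, cols, drop = FALSE]
  canvas[rows, cols] <- pmax(sub, matrix(v, nrow = length(rows)))
  canvas
}
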