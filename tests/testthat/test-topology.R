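test_that("a straight line is one edge with two free ends", {
  m <- put_pixels(matrix(0L, 12, 16), digital_line(6, 4, 6, 13))
  g <- build_graph(m)
  expect_length(g$edges, 1L)
  expect_equal(nrow(g$edges[[1]]$pixels), 10L)
  expect_true(all(is.na(g$edges[[1]]$clusters)))
  expect_equal(nrow(g$endpoints), 2L)
  expect_length(g$clusters, 0L)
})

test_that("a plus sign is one junction with four incident edges", {
  m <- matrix(0L, 15, 15)
  m <- put_pixels(m, digital_line(8, 3, 8, 13))
  m <- put_pixels(m, digital_line(3, 8, 13, 8))
  g <- build_graph(m)
  expect_length(g$clusters, 1L)
  real <- Filter(function(e) !e$is_stub, g$edges)
  expect_length(real, 4L)
  # every pixel of the skeleton appears in exactly one chain
  allpx <- do.call(rbind, lapply(g$edges, function(e) e$pixels))
  expect_equal(nrow(allpx), sum(m))
  expect_false(any(duplicated(allpx)))
})

test_that("a closed ring is a single cycle edge with no nodes", {
  # diamond ring |dr| + |dc| = 5: 20 pixels, every one of degree 2
  m <- matrix(0L, 13, 13)
  for (dr in -5:5) for (dc in -5:5)
    if (abs(dr) + abs(dc) == 5L) m[7 + dr, 7 + dc] <- 1L
  g <- build_graph(m)
  expect_length(g$clusters, 0L)
  expect_length(g$edges, 1L)
  expect_true(g$edges[[1]]$is_cycle)
  expect_equal(nrow(g$edges[[1]]$pixels), 20L)
  paths <- disambiguate(g)
  expect_length(paths, 1L)
  expect_true(paths[[1]]$closed)
})

test_that("skeleton pixels partition into chains on random skeletons", {
  for (seed in 1:25) {
    sk <- random_skeleton(seed)
    g <- build_graph(sk)
    allpx <- do.call(rbind, lapply(g$edges, function(e) e$pixels))
    expect_equal(nrow(allpx), g$n_pixels)
    expect_false(any(duplicated(allpx)))
  }
})

test_that("an X crossing resolves into the two collinear pairings", {
  m <- matrix(0L, 25, 25)
  m <- put_pixels(m, digital_line(13, 3, 13, 23))   # horizontal
  m <- put_pixels(m, digital_line(3, 13, 23, 13))   # vertical
  g <- build_graph(m)
  paths <- disambiguate(g)
  real <- Filter(function(p) !p$debris, paths)
  expect_length(real, 2L)
  spans <- lapply(real, function(p) apply(p$pixels, 2, range))
  # one path spans the full horizontal extent, the other the vertical
  horiz <- vapply(spans, function(s) diff(s[, 2]) > 15 && diff(s[, 1]) < 5, TRUE)
  vert <- vapply(spans, function(s) diff(s[, 1]) > 15 && diff(s[, 2]) < 5, TRUE)
  expect_equal(sum(horiz), 1L)
  expect_equal(sum(vert), 1L)

  # enumeration oracle: over the three perfect pairings of the four branch
  # directions, the collinear pairing minimizes the total turn angle
  dirs <- list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0))  # W, E, N, S tangents
  turn <- function(a, b) 180 - acos(pmin(1, pmax(-1, sum(a * b)))) * 180 / pi
  pairings <- list(rbind(c(1, 2), c(3, 4)), rbind(c(1, 3), c(2, 4)),
                   rbind(c(1, 4), c(2, 3)))
  tot <- vapply(pairings, function(p)
    sum(apply(p, 1, function(ij) turn(dirs[[ij[1]]], dirs[[ij[2]]]))), 1)
  expect_equal(which.min(tot), 1L)   # W-E with N-S
})

test_that("a Y junction merges the near-collinear pair and leaves the third", {
  m <- matrix(0L, 30, 40)
  m <- put_pixels(m, digital_line(15, 3, 15, 20))    # straight left arm
  m <- put_pixels(m, digital_line(15, 21, 18, 38))   # right arm, ~10 deg down
  m <- put_pixels(m, digital_line(14, 21, 3, 23))    # steep arm, ~80 deg
  g <- build_graph(m)
  paths <- Filter(function(p) !p$debris, disambiguate(g))
  expect_length(paths, 2L)
  lens <- sort(vapply(paths, function(p) nrow(p$pixels), 1L))
  expect_gt(lens[2], 30L)   # merged collinear pair
  expect_lt(lens[1], 16L)   # lone steep arm
})

test_that("an isolated edge passes through unchanged", {
  m <- put_pixels(matrix(0L, 10, 20), digital_line(5, 3, 5, 17))
  paths <- disambiguate(build_graph(m))
  expect_length(paths, 1L)
  expect_equal(nrow(paths[[1]]$pixels), 15L)
})

test_that("path_length follows the chain metric", {
  expect_equal(path_length(cbind(1, 1:10)), 9)
  expect_equal(path_length(cbind(1:10, 1:10)), 9 * sqrt(2))
  chain <- rbind(cbind(1, 1:6), cbind(2:5, 7:10))
  expect_equal(path_length(chain), 5 + 4 * sqrt(2))
  expect_equal(path_length(cbind(1, 1:10), pixel_size_um = 0.2), 1.8)
  expect_equal(path_length(matrix(c(3, 4), 1, 2)), 0)
})

test_that("pixels and total length are conserved through disambiguation", {
  for (seed in 1:100) {
    sk <- random_skeleton(seed)
    g <- build_graph(sk)
    paths <- disambiguate(g)
    npx <- sum(vapply(paths, function(p) nrow(p$pixels), 1L))
    expect_equal(npx, attr(paths, "n_skeleton_px"))
    core <- sum(vapply(paths, function(p)
      p$length_px - p$joint_px - p$gap_px, 1))
    expect_equal(core, attr(paths, "total_edge_px"), tolerance = 1e-9)
  }
})

test_that("disambiguation is deterministic", {
  sk <- random_skeleton(7)
  a <- disambiguate(build_graph(sk))
  b <- disambiguate(build_graph(sk))
  expect_identical(lapply(a, `[[`, "pixels"), lapply(b, `[[`, "pixels"))
})
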