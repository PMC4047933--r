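test_that("bimodal values split exactly, agreeing with a threshold-sweep oracle", {
  withr::with_seed(23, {
    v <- matrix(0.1, 40, 40)
    hi <- sample(length(v), 160)
    v[hi] <- 0.9
  })
  fg <- estimate_foreground(v, min_object_px = 1L)
  expect_identical(which(fg$mask == 1L), sort(hi))

  # oracle: exhaustive threshold sweep minimizing within-class variance
  vals <- sort(unique(as.vector(v)))
  cuts <- (vals[-1] + vals[-length(vals)]) / 2
  wcv <- vapply(cuts, function(t) {
    lo <- v[v < t]; hi2 <- v[v >= t]
    sum((lo - mean(lo))^2) + sum((hi2 - mean(hi2))^2)
  }, 1)
  t_star <- cuts[which.min(wcv)]
  expect_identical(fg$mask == 1L, v >= t_star)
})

test_that("clustering reduces to a single threshold", {
  withr::with_seed(29, v <- matrix(runif(64 * 64)^3, 64, 64))
  fg <- estimate_foreground(v, min_object_px = 1L)
  expect_identical(fg$mask == 1L, v >= fg$threshold)
})

test_that("the mask is invariant to constant shifts of the likelihood", {
  withr::with_seed(31, v <- matrix(runif(32 * 32)^2, 32, 32))
  a <- estimate_foreground(v, min_object_px = 1L)
  b <- estimate_foreground(v + 0.37, min_object_px = 1L)
  expect_identical(a$mask, b$mask)
})

test_that("degenerate constant input warns and returns all background", {
  expect_warning(fg <- estimate_foreground(matrix(0.5, 16, 16)), "degenerate")
  expect_true(all(fg$mask == 0L))
})

test_that("small components are removed", {
  v <- matrix(0.02, 64, 64)
  v[20:22, 10:40] <- 0.9      # large ridge-like component
  v[50, 50] <- 0.9            # speck
  fg <- estimate_foreground(v, min_object_px = 20L)
  expect_equal(fg$mask[50, 50], 0L)
  expect_true(all(fg$mask[20:22, 10:40] == 1L))
})

test_that("mask covers the true centerline of a noise-free filament", {
  sc <- render_straight(0.7, length_px = 60)
  lik <- enhance(sc$image, tiny_bank())
  fg <- estimate_foreground(lik, 20L)
  px <- unique(round(sc$centerline))
  expect_gte(mean(fg$mask[px] == 1L), 0.95)
})

test_that("label8 agrees with an independent graph-component oracle", {
  for (seed in 1:10) {
    m <- random_blob_mask(seed, 24L)
    lab <- label8(m)
    # oracle: connected components of the 8-adjacency graph via igraph
    px <- which(m == 1L, arr.ind = TRUE)
    n <- nrow(px)
    if (n == 0) { expect_equal(max(lab), 0L); next }
    adj <- which(outer(px[, 1], px[, 1], function(a, b) abs(a - b)) <= 1 &
                 outer(px[, 2], px[, 2], function(a, b) abs(a - b)) <= 1,
                 arr.ind = TRUE)
    adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
    g <- igraph::graph_from_edgelist(adj, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    expect_equal(max(lab), igraph::components(g)$no)
    # pixels sharing an igraph component share a label
    comp <- igraph::components(g)$membership
    expect_equal(length(unique(paste(comp, lab[px]))), max(lab))
  }
})
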