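test_that("spec validation rejects impossible parameter combinations", {
  expect_error(network_spec(length_mean_px = -1), "length_mean_px")
  expect_error(network_spec(image_height_px = 0), "positive area")
  expect_error(network_spec(min_length_px = 200, length_mean_px = 50,
                            length_sd_px = 20), "plausible")
  expect_error(network_spec(width_sigma_px = 0), "width_sigma_px")
})

test_that("degenerate length distribution gives constant-length filaments", {
  spec <- network_spec(image_height_px = 512L, image_width_px = 512L,
                      length_sd_px = 0, length_mean_px = 50,
                      curvature_max_per_px = 0, seed = 5L)
  withr::with_seed(11, {
    for (i in 1:20) {
      f <- sample_filament(spec)
      interior <- all(f$centerline >= 2 & f$centerline <= 511)
      if (interior) expect_equal(f$length_px, 50, tolerance = 0.01)
    }
  })
})

test_that("sampled lengths follow the truncated Gaussian", {
  # big frame so border clipping is negligible
  spec <- network_spec(image_height_px = 1024L, image_width_px = 1024L,
                      length_mean_px = 50, length_sd_px = 20,
                      min_length_px = 10, seed = 2L)
  lens <- withr::with_seed(7, vapply(seq_len(2000), function(i)
    sample_filament(spec)$length_px, 1))
  # theoretical mean of a Normal(50, 20) truncated below at 10
  a <- (10 - 50) / 20
  mu_trunc <- 50 + 20 * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(lens), mu_trunc, tolerance = 3 * 20 / sqrt(2000) / mu_trunc)
  expect_true(all(lens >= 10))
  # paper's bank conditions: mean of drawn lengths close to 50
  expect_lt(abs(mean(lens) - 50), 2)
})

test_that("ground-truth length equals centerline arc length", {
  spec <- network_spec(seed = 3L)
  withr::with_seed(13, {
    for (i in 1:10) {
      f <- sample_filament(spec)
      if (nrow(f$centerline) >= 2)
        expect_equal(f$length_px,
                     filatrace:::polyline_length(f$centerline),
                     tolerance = 1e-9)
    }
  })
})

test_that("rendering is deterministic and honours the spec", {
  spec <- network_spec(n_filaments = 4, seed = 21L)
  a <- render_network(spec)
  b <- render_network(spec)
  expect_identical(a$image, b$image)
  expect_identical(lapply(a$truth$filaments, `[[`, "centerline"),
                   lapply(b$truth$filaments, `[[`, "centerline"))
  expect_length(a$truth$filaments, 4L)
})

test_that("empty network renders background plus noise only", {
  net <- render_network(network_spec(n_filaments = 0L, noise_sd = 0,
                                     background_level = 7, seed = 1L))
  expect_length(net$truth$filaments, 0L)
  expect_true(all(net$image == 7))
})

test_that("a noise-free ridge peaks on its centerline", {
  canvas <- matrix(0, 64, 64)
  poly <- filatrace:::arc_polyline(32, 32, 0, 0, 40, 0.5)  # horizontal row 32
  img <- filatrace:::add_ridge(canvas, poly, 1.5, 100) + 10
  # pixel centers on the centerline carry exactly background + peak
  expect_equal(img[32, 20], 110, tolerance = 1e-6)
  expect_equal(img[32, 40], 110, tolerance = 1e-6)
  # the maximum of every crossing column lies on the true row
  for (cc in seq(15, 49, by = 5))
    expect_equal(which.max(img[, cc]), 32L)
})

test_that("total intensity grows with filament count (no noise, no background)", {
  tot <- vapply(c(1L, 4L, 8L), function(n) {
    spec <- network_spec(n_filaments = n, noise_sd = 0, background_level = 0,
                        seed = 31L)
    sum(render_network(spec)$image)
  }, 1)
  expect_true(all(diff(tot) > 0))
})

test_that("validation bank has the requested layout and is reproducible", {
  base <- network_spec()
  bank <- validation_bank(base, density_levels = c(2L, 4L),
                          images_per_level = 3L, seed = 9L)
  expect_length(bank, 6L)
  expect_equal(vapply(bank, function(x) length(x$truth$filaments), 1L),
               c(2L, 2L, 2L, 4L, 4L, 4L))
  bank2 <- validation_bank(base, density_levels = c(2L, 4L),
                           images_per_level = 3L, seed = 9L)
  expect_identical(lapply(bank, `[[`, "image"), lapply(bank2, `[[`, "image"))
  single <- validation_bank(base, density_levels = 1L,
                            images_per_level = 1L, seed = 4L)
  expect_length(single, 1L)
  expect_length(single[[1]]$truth$filaments, 1L)
})

test_that("placement rejects tangential contacts but keeps transversal ones", {
  net <- render_network(network_spec(n_filaments = 12L, seed = 17L))
  fil <- net$truth$filaments
  for (i in seq_len(length(fil) - 1)) {
    expect_true(filatrace:::is_resolvable(fil[[i]], fil[-i]))
  }
})
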