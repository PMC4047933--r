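test_that("constant images yield zero response and zero likelihood", {
  img <- matrix(5, 64, 64)
  br <- best_response(img, tiny_bank())
  # zero-mean kernels are orthogonal to constants; only the zero-padded
  # border band (flagged invalid) responds
  expect_true(all(abs(br$response[br$valid]) < 1e-6))
  lik <- enhance(img, tiny_bank())
  expect_true(all(lik$values == 0))
})

test_that("response is invariant to constant offsets away from the border", {
  net <- render_network(network_spec(n_filaments = 2, seed = 41L))
  a <- best_response(net$image, tiny_bank())
  b <- best_response(net$image + 37, tiny_bank())
  v <- a$valid
  expect_equal(a$response[v], b$response[v], tolerance = 1e-6)
})

test_that("winning rotation matches a dense brute-force sweep", {
  # oracle: correlation of the centre patch against templates at a dense
  # 3-degree rotation sweep, computed directly as a dot product
  theta_true <- 30 * pi / 180
  sc <- render_straight(theta_true, length_px = 60)
  bank <- default_bank()   # 12 rotations, bin pi/12
  br <- best_response(sc$image, bank)
  centre <- c(64, 64)
  got <- br$best_rotation_rad[centre[1], centre[2]]

  sweep <- seq(0, pi, by = 3 * pi / 180)
  k0 <- filatrace:::render_template(15, 1.5, 0, 0)
  h <- (nrow(k0) - 1) / 2
  patch_at <- function(img, r, c, h)
    img[(r - h):(r + h), (c - h):(c + h)]
  scores <- vapply(sweep, function(th) {
    k <- filatrace:::render_template(15, 1.5, 0, th)
    hh <- (nrow(k) - 1) / 2
    sum(patch_at(sc$image, centre[1], centre[2], hh) * k)
  }, 1)
  oracle <- sweep[which.max(scores)]
  expect_lt(abs(got - oracle), pi / 12 + 1e-9)
  expect_lt(min(abs(got - theta_true), pi - abs(got - theta_true)), pi / 12)
})

test_that("winning rotation tracks orientation over random filaments", {
  bank <- default_bank()
  withr::with_seed(19, thetas <- runif(6, 0, pi))
  for (theta in thetas) {
    sc <- render_straight(theta, length_px = 60)
    br <- best_response(sc$image, bank)
    got <- br$best_rotation_rad[64, 64]
    d <- abs(got - theta)
    expect_lt(min(d, pi - d), pi / 12 + 1e-9)
  }
})

test_that("a diffuse blob is suppressed despite high intensity", {
  # blob much wider than any template footprint: ridge response stays low
  g <- outer(1:128, 1:128, function(r, c) exp(-((r - 64)^2 + (c - 64)^2) / (2 * 30^2)))
  sc <- render_straight(0.5, length_px = 50, mid = c(30, 30))
  img <- pmax(sc$image, 10 + 100 * g)
  br <- best_response(img, tiny_bank())
  expect_lt(br$response[64, 64] / max(br$response), 0.1)
  lik <- likelihood_image(br$response, img)
  expect_lt(lik[64, 64], 0.1)
})

test_that("likelihood is a product of min-max normalized maps in [0, 1]", {
  net <- render_network(network_spec(n_filaments = 3, seed = 43L))
  lik <- enhance(net$image, tiny_bank())
  expect_true(all(lik$values >= 0 & lik$values <= 1))
  expect_error(likelihood_image(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("likelihood ridge follows the true centerline", {
  sc <- render_straight(0, length_px = 80)   # horizontal, row 64
  lik <- enhance(sc$image, tiny_bank())
  cols <- 30:98
  hit <- vapply(cols, function(cc) abs(which.max(lik$values[, cc]) - 64) <= 1,
                TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("background likelihood is far below centerline likelihood", {
  net <- render_network(network_spec(n_filaments = 3, noise_sd = 10,
                                     seed = 47L))
  lik <- enhance(net$image, default_bank())
  on_mask <- matrix(FALSE, 128, 128)
  for (f in net$truth$filaments) {
    px <- unique(round(f$centerline))
    px <- px[px[, 1] >= 1 & px[, 1] <= 128 & px[, 2] >= 1 & px[, 2] <= 128, ,
             drop = FALSE]
    on_mask[px] <- TRUE
  }
  near <- EBImage::filter2(on_mask * 1, matrix(1, 9, 9), boundary = 0) > 0
  bg <- !near & lik$valid
  expect_lt(mean(lik$values[bg]), 0.1 * mean(lik$values[on_mask]))
})
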