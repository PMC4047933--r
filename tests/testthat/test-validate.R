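test_that("count relative error follows its formula", {
  expect_equal(count_relative_error(97, 100), 0.03)
  expect_equal(count_relative_error(100, 100), 0)
  expect_equal(count_relative_error(52, 50), 0.04)
  expect_error(count_relative_error(5, 0), "n_true")
})

test_that("length RMSE follows its formula", {
  mk_paths <- function(lens) lapply(lens, function(L)
    list(pixels = cbind(1, 1:2), length_px = L))
  mk_truth <- function(lens) list(filaments = lapply(lens, function(L)
    list(centerline = cbind(1, 1:2), length_px = L)))
  m <- data.frame(pred_index = 1:2, truth_index = 1:2, dist_px = 0)
  expect_equal(length_rmse(m, mk_paths(c(10, 20)), mk_truth(c(10, 20))), 0)
  m1 <- data.frame(pred_index = 1, truth_index = 1, dist_px = 0)
  expect_equal(length_rmse(m1, mk_paths(53), mk_truth(50)), 3)
  expect_equal(length_rmse(m, mk_paths(c(13, 24)), mk_truth(c(10, 20))),
               sqrt(12.5))
  expect_warning(r <- length_rmse(m[0, ], mk_paths(10), mk_truth(10)),
                 "no matched")
  expect_true(is.na(r))
})

test_that("matching is one-to-one and distance-gated", {
  line <- function(r) cbind(r, 10:40)
  truth <- list(filaments = lapply(c(10, 30, 50), function(r)
    list(centerline = line(r), length_px = 30)))
  pred_exact <- lapply(c(10, 30, 50), function(r)
    list(pixels = line(r), length_px = 30))
  m <- match_filaments(pred_exact, truth)
  expect_equal(nrow(m), 3L)
  expect_true(all(m$dist_px < 1e-9))
  expect_equal(m$truth_index[order(m$pred_index)], 1:3)

  far <- list(list(pixels = line(100), length_px = 30))
  expect_equal(nrow(match_filaments(far, list(filaments = truth$filaments[1]))),
               0L)
})

test_that("matching recovers the spatially correct pairing under permutation", {
  line <- function(r) cbind(r, 10:40)
  truth <- list(filaments = lapply(c(10, 30, 50), function(r)
    list(centerline = line(r), length_px = 30)))
  pred <- lapply(c(30, 50, 10), function(r)        # permuted, 1 px jitter
    list(pixels = line(r + 1), length_px = 30))
  m <- match_filaments(pred, truth)
  got <- m$truth_index[order(m$pred_index)]
  expect_equal(got, c(2L, 3L, 1L))

  # brute-force oracle over all 3! assignments
  D <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    D[i, j] <- filatrace:::symmetric_mean_dist(pred[[i]]$pixels,
                                               truth$filaments[[j]]$centerline)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  tot <- vapply(perms, function(p) sum(D[cbind(1:3, p)]), 1)
  expect_equal(got, perms[[which.min(tot)]])
})

test_that("noise-free sparse straight networks validate perfectly", {
  # seeds chosen so that the three filaments are pairwise > 12 px apart
  # (verified below), hence non-intersecting by construction
  bank <- lapply(c(3L, 4L), function(s)
    render_network(network_spec(n_filaments = 3, noise_sd = 0, seed = s)))
  for (net in bank) {
    fil <- net$truth$filaments
    for (i in 1:2) for (j in (i + 1):3) {
      A <- fil[[i]]$centerline; B <- fil[[j]]$centerline
      dmin <- sqrt(min(outer(A[, 1], B[, 1], "-")^2 +
                         outer(A[, 2], B[, 2], "-")^2))
      expect_gt(dmin, 12)
    }
  }
  rep <- run_validation(bank, tiny_bank())
  expect_equal(rep$max_count_rel_error, 0)
  expect_lt(rep$max_length_rmse_px, 5)
})

test_that("validation is deterministic and rejects empty banks", {
  expect_error(run_validation(list()), "length")
  bank <- validation_bank(network_spec(), density_levels = 2L,
                          images_per_level = 2L, seed = 5L)
  a <- run_validation(bank, tiny_bank())
  b <- run_validation(bank, tiny_bank())
  expect_identical(a$per_image, b$per_image)
  expect_equal(a$max_count_rel_error, max(a$per_image$count_rel_error))
  expect_equal(a$max_length_rmse_px,
               max(a$per_image$length_rmse_px, na.rm = TRUE))
})
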