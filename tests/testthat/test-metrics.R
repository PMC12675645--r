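test_that("rmse matches its closed forms and the loop oracle", {
  gt <- cbind(x = rnorm(10), y = rnorm(10))
  expect_equal(rmse(gt, gt), 0)
  off <- sweep(gt, 2, c(-3, -4))
  expect_equal(rmse(off, gt), 5.0)
  set.seed(12)
  tr <- cbind(x = rnorm(10), y = rnorm(10))
  loop <- 0
  for (t_ in 1:10)
    loop <- loop + (gt[t_, 1] - tr[t_, 1])^2 + (gt[t_, 2] - tr[t_, 2])^2
  expect_equal(rmse(tr, gt), sqrt(unname(loop) / 10))
  expect_error(rmse(tr[1:5, ], gt), "length")
  # translation consistency: offsetting the track re-derives the loop value
  tr2 <- sweep(tr, 2, c(-1.5, 2))
  loop2 <- 0
  for (t_ in 1:10)
    loop2 <- loop2 + (gt[t_, 1] - tr2[t_, 1])^2 + (gt[t_, 2] - tr2[t_, 2])^2
  expect_equal(rmse(tr2, gt), sqrt(unname(loop2) / 10))
})

test_that("tsr counts strict successes against the 25% threshold", {
  expect_equal(tsr(rep(0, 7), motion_range = 10), 100)
  expect_equal(tsr(c(1, 3, 2, 5), motion_range = 10), 50)
  # errors exactly at the threshold do not count (strict inequality)
  expect_equal(tsr(rep(2.5, 4), motion_range = 10), 0)
  expect_error(tsr(c(1, 2), motion_range = 0), "positive")
  # monotone non-increasing as the range shrinks
  err <- c(0.5, 1, 1.5, 2, 3)
  ranges <- c(16, 8, 4, 2)
  vals <- vapply(ranges, function(r) tsr(err, motion_range = r), 0)
  expect_true(all(diff(vals) <= 0))
})

test_that("psnr matches the 8-bit closed forms", {
  a <- matrix(100, 4, 4)
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 1), 20 * log10(255), tolerance = 1e-12)
  expect_equal(psnr(a, a + 1), 48.13, tolerance = 1e-3)
  expect_equal(psnr(a, a + 2), 48.1308 - 10 * log10(4), tolerance = 1e-3)
  expect_error(psnr(a, matrix(0, 2, 2)), "shape")
  # strictly decreasing in MSE
  set.seed(3)
  noise <- matrix(rnorm(16), 4, 4)
  vals <- vapply(c(0.5, 1, 2, 4), function(s) psnr(a, a + s * noise), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("ssim satisfies identity, symmetry, and degenerate cases", {
  set.seed(8)
  a <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(ssim(a, a), 1.0)
  b <- a + matrix(rnorm(32 * 32, 0, 20), 32, 32)
  expect_equal(ssim(a, b), ssim(b, a), tolerance = 1e-12)
  expect_lt(ssim(a, b), 1)
  expect_gt(ssim(a, b), -1)
  expect_equal(ssim(matrix(7, 16, 16), matrix(7, 16, 16)), 1.0)
  expect_error(ssim(a, a[1:16, ]), "shape")
})

test_that("ssim agrees with a direct windowed implementation", {
  # independent oracle: explicit Gaussian-weighted moments at a few pixels
  set.seed(14)
  a <- matrix(runif(24 * 24, 0, 1), 24, 24)
  b <- a + matrix(rnorm(24 * 24, 0, 0.1), 24, 24)
  g1 <- exp(-((-5:5)^2) / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  K <- outer(g1, g1)
  vals <- matrix(NA_real_, 14, 14)
  for (r in 6:19) for (c in 6:19) {
    wa <- a[(r - 5):(r + 5), (c - 5):(c + 5)]
    wb <- b[(r - 5):(r + 5), (c - 5):(c + 5)]
    mu_a <- sum(K * wa); mu_b <- sum(K * wb)
    va <- sum(K * wa^2) - mu_a^2; vb <- sum(K * wb^2) - mu_b^2
    cab <- sum(K * wa * wb) - mu_a * mu_b
    c1 <- (0.01 * 1)^2; c2 <- (0.03 * 1)^2
    vals[r - 5, c - 5] <- (2 * mu_a * mu_b + c1) * (2 * cab + c2) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  }
  expect_equal(ssim(a, b, max_value = 1), mean(vals), tolerance = 1e-12)
})

test_that("paired bootstrap separates what should be separated", {
  set.seed(19)
  e <- abs(rnorm(80, 2, 0.3))
  same <- paired_bootstrap_test(e, e, B = 500, seed = 1)
  expect_gt(same$p_value, 0.9)
  expect_false(same$reject)

  a <- abs(rnorm(100, 1, 0.1))
  b <- abs(rnorm(100, 5, 0.1))
  sep <- paired_bootstrap_test(a, b, B = 1000, seed = 2)
  expect_true(sep$reject)
  expect_lt(sep$p_value, 0.05)
  expect_lt(sep$ci_a[2], sep$ci_b[1])

  # seeded determinism
  sep2 <- paired_bootstrap_test(a, b, B = 1000, seed = 2)
  expect_identical(sep$p_value, sep2$p_value)
  expect_identical(sep$ci_a, sep2$ci_a)

  # TSR statistic variant
  ts <- paired_bootstrap_test(a, b, B = 500, statistic = "tsr",
                              motion_range = 10, seed = 3)
  expect_true(ts$reject)
  expect_error(paired_bootstrap_test(a, b[1:50]), "length")
  expect_error(paired_bootstrap_test(a, b, B = 50), "B must")
})

test_that("tracking_report summarizes errors consistently", {
  rep_ <- tracking_report(c(1, 3, 2, 5), motion_range = 10)
  expect_equal(rep_$rmse, sqrt(mean(c(1, 9, 4, 25))))
  expect_equal(rep_$tsr, 50)
  expect_equal(rep_$success_threshold, 2.5)
})
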