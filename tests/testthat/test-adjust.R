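test_that("affine registration recovers known transforms", {
  drr <- blob_image(64, cx = 40, cy = 28)
  # identical images: identity transform
  tf0 <- affine_register(drr, drr)
  expect_lt(abs(tf0$tx), 0.1)
  expect_lt(abs(tf0$ty), 0.1)
  expect_lt(abs(tf0$rotation), 0.05)
  expect_lt(abs(tf0$scale - 1), 0.005)

  # frame shifted by a known translation: the inverse shift is recovered
  # within 0.5 px (the transform maps DRR geometry into frame geometry)
  frame <- fluorodes:::.warp_affine2d_cpp(drr, 5, 3, 0, 1)
  tf <- affine_register(drr, frame)
  expect_lt(abs(tf$tx - (-5)), 0.5)
  expect_lt(abs(tf$ty - (-3)), 0.5)
  # and the resampled frame matches the DRR again
  back <- apply_affine(frame, tf)
  inner <- 17:48
  expect_lt(mean(abs(back[inner, inner] - drr[inner, inner])), 0.02)

  # rotation + scale: inverse parameters recovered within 0.2 deg / 0.01
  frame2 <- fluorodes:::.warp_affine2d_cpp(drr, 0, 0, 2, 1.05)
  tf2 <- affine_register(drr, frame2)
  expect_lt(abs(tf2$rotation - (-2)), 0.2)
  expect_lt(abs(tf2$scale - 1 / 1.05), 0.01)
})

test_that("registration divergence returns identity with a warning", {
  set.seed(5)
  a <- matrix(runif(32 * 32), 32, 32)
  b <- matrix(runif(32 * 32), 32, 32)
  expect_warning(tf <- affine_register(a, b, min_similarity = 0.999),
                 "registration")
  expect_equal(tf$tx, 0)
  expect_equal(tf$scale, 1)
})

test_that("histogram matching aligns CDFs monotonically", {
  # self-reference: identity up to 8-bit quantization
  img <- blob_image(32)
  out <- histogram_match(img, img)
  expect_lt(max(abs(out - norm01(img))), 1 / 255 + 1e-12)

  # constant reference collapses to the constant
  out_c <- histogram_match(img, matrix(0.4, 8, 8))
  expect_true(all(out_c == 0.4))

  # exactly uniform input histogram vs a wide-Gaussian reference
  set.seed(3)
  uni <- matrix(sample(rep(0:255, 16)) / 255, 64, 64)
  ref <- matrix(stats::qnorm(stats::ppoints(4096), 0.5, 0.18), 64, 64)
  ref <- pmin(pmax(ref, 0), 1)
  out_u <- histogram_match(uni, ref)
  q_out <- round(out_u * 255)
  q_ref <- round(norm01(ref) * 255)
  cdf_out <- cumsum(tabulate(q_out + 1, 256)) / 4096
  cdf_ref <- cumsum(tabulate(q_ref + 1, 256)) / 4096
  expect_lt(max(abs(cdf_out - cdf_ref)), 1 / 256 + 1e-12)

  # monotone: intensity order is never inverted
  ord <- order(as.numeric(uni))
  expect_true(all(diff(as.numeric(out_u)[ord]) >= 0))
  # geometry unchanged
  expect_identical(dim(out_u), dim(uni))
})

test_that("median smoothing matches the brute-force 5x5 median", {
  expect_equal(median_smooth(matrix(0.7, 9, 9)), matrix(0.7, 9, 9))
  imp <- matrix(0.2, 11, 11)
  imp[6, 6] <- 1
  expect_true(all(median_smooth(imp) == 0.2))

  set.seed(17)
  x <- matrix(runif(49), 7, 7)
  got <- median_smooth(x)
  reflect <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  want <- x
  for (r in 1:7) for (c in 1:7) {
    vals <- numeric(0)
    for (dr in -2:2) for (dc in -2:2)
      vals <- c(vals, x[reflect(r + dr, 7), reflect(c + dc, 7)])
    want[r, c] <- stats::median(vals)
  }
  expect_equal(got, want)
})

test_that("adjust_sequence standardizes frames toward the DRR", {
  drr <- blob_image(64, cx = 44, cy = 24)
  # the DRR itself passes through nearly unchanged (identity path)
  out <- adjust_sequence(list(drr), drr)
  expect_lt(mean(abs(out[[1]] - norm01(drr))), 0.05)

  # per-frame output quantiles track the DRR quantiles (histogram matching
  # survives the 5x5 median smoothing up to a few gray levels)
  frames <- list(drr^1.4, 0.2 + 0.7 * drr)
  adj <- adjust_sequence(frames, drr, register = FALSE)
  probs <- seq(0.1, 0.9, by = 0.1)
  q_ref <- quantile(norm01(drr), probs)
  for (f in adj) {
    expect_identical(dim(f), dim(drr))
    expect_lt(max(abs(quantile(f, probs) - q_ref)), 5 / 255)
  }
  # before smoothing, the match is within one gray level at every quantile
  hm <- histogram_match(frames[[1]], drr)
  expect_lt(max(abs(quantile(hm, probs) - q_ref)), 1 / 255 + 1e-12)

  # idempotence up to smoothing: re-adjusting changes little
  twice <- adjust_sequence(adj, drr, register = FALSE)
  expect_lt(mean(abs(twice[[1]] - adj[[1]])), 2 / 255)
})
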