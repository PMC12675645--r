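test_that("model building is seeded and shape preserving", {
  cfg <- unet_config(depth = 2, base_filters = 4, input_shape = c(16, 16),
                     epochs = 1, seed = 13, coord_channels = FALSE)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  x <- matrix(runif(256), 16, 16)
  out <- fluorodes:::unet_forward(m1$params, x, 2)$pred
  expect_identical(dim(out), c(16L, 16L))
  expect_error(unet_config(depth = 3, input_shape = c(20, 20)), "divisible")
})

test_that("parameter count equals the layer-by-layer hand tally", {
  # depth 3, base 8, one residual block per level; every 3x3 conv has
  # 9*c_in*c_out weights + c_out biases, channel-changing blocks add a 1x1
  # projection with c_in*c_out weights
  resblock <- function(c_in, c_out) {
    9 * c_in * c_out + c_out +      # conv1
      9 * c_out * c_out + c_out +   # conv2
      (if (c_in != c_out) c_in * c_out else 0)
  }
  tally <- resblock(1, 8) +         # encoder level 1
    resblock(8, 16) +               # encoder level 2
    resblock(16, 32) +              # bottleneck
    resblock(16 + 32, 16) +         # decoder level 2 (skip 16 + up 32)
    resblock(8 + 16, 8) +           # decoder level 1 (skip 8 + up 16)
    (8 * 1 + 1)                     # final 1x1 conv
  m <- build_model(unet_config(depth = 3, base_filters = 8,
                               input_shape = c(64, 64),
                               coord_channels = FALSE))
  expect_identical(n_parameters(m), tally)
  # the two optional coordinate channels add 9*2*8 first-conv weights and
  # widen the first projection from 1x8 to 3x8
  m2 <- build_model(unet_config(depth = 3, base_filters = 8,
                                input_shape = c(64, 64),
                                coord_channels = TRUE))
  expect_identical(n_parameters(m2), tally + 9 * 2 * 8 + 2 * 8)
})

test_that("mse_loss matches its closed forms and the loop oracle", {
  a <- matrix(runif(9), 3, 3)
  expect_identical(mse_loss(a, a), 0)
  expect_equal(mse_loss(a, a + 2), 4)
  b <- matrix(runif(9), 3, 3)
  loop <- 0
  for (i in 1:3) for (j in 1:3) loop <- loop + (b[i, j] - a[i, j])^2
  expect_equal(mse_loss(a, b), loop / 9)
  expect_equal(mse_loss(a, b), mse_loss(b, a))
  expect_error(mse_loss(a, matrix(0, 2, 2)), "shape")
})

test_that("learning rate decays linearly between the endpoints", {
  cfg <- unet_config(initial_lr = 0.02, final_lr = 1e-4, epochs = 11)
  expect_equal(lr_schedule(cfg, 1), 0.02)
  expect_equal(lr_schedule(cfg, 11), 1e-4)
  expect_lt(abs(lr_schedule(cfg, 6) - (0.02 + 1e-4) / 2), 1e-9)
})

test_that("analytic gradients match finite differences", {
  set.seed(31)
  cfg <- unet_config(depth = 2, base_filters = 2, input_shape = c(8, 8),
                     epochs = 1, seed = 3, coord_channels = FALSE)
  m <- build_model(cfg)
  x <- matrix(runif(64), 8, 8)
  y <- matrix(runif(64), 8, 8)
  fw <- fluorodes:::unet_forward(m$params, x, 2)
  gr <- fluorodes:::unet_backward(m$params, fw$cache,
                                  2 * (fw$pred - y) / 64, 2)
  modify <- function(tree, path, i, d) {
    if (length(path) == 1) {
      tree[[path[[1]]]][i] <- tree[[path[[1]]]][i] + d
      tree
    } else {
      tree[[path[[1]]]] <- modify(tree[[path[[1]]]], path[-1], i, d)
      tree
    }
  }
  eps <- 1e-6
  for (path in list(list("enc", 1, 1, "W1"), list("enc", 2, 1, "b2"),
                    list("dec", 1, 1, "P"), list("final", "W"))) {
    g <- gr
    for (k in path) g <- g[[k]]
    i <- sample(length(g), 1)
    f <- function(d)
      mse_loss(fluorodes:::unet_forward(modify(m$params, path, i, d),
                                        x, 2)$pred, y)
    num <- (f(eps) - f(-eps)) / (2 * eps)
    expect_lt(abs(g[i] - num) / max(abs(num), 1e-8), 1e-5)
  }
})

test_that("zero epochs leaves the initialization untouched", {
  cfg <- unet_config(depth = 2, base_filters = 2, input_shape = c(16, 16),
                     epochs = 0, seed = 8)
  m <- build_model(cfg)
  pair <- tiny_pair()
  pair$se$pixels <- pair$se$pixels[1:16, 1:16]
  pair$des$pixels <- pair$des$pixels[1:16, 1:16]
  trained <- train_synthesizer(m, list(pair))
  expect_identical(trained$params, m$params)
  expect_identical(nrow(trained$history), 0L)
})

test_that("a small model overfits a single pair", {
  # without the global shortcut, so the optimizer must fit the full image
  cfg <- unet_config(depth = 2, base_filters = 4, input_shape = c(16, 16),
                     epochs = 200, batch_size = 1, seed = 21,
                     global_skip = FALSE)
  pair <- tiny_pair()
  pair$se$pixels <- pair$se$pixels[9:24, 9:24]
  pair$des$pixels <- pair$des$pixels[9:24, 9:24]
  m <- train_synthesizer(build_model(cfg), list(pair))
  # 200 epochs on one pair = 200 Adam steps; the loss falls by over two
  # orders of magnitude and is still decreasing (extending the run to 1000
  # steps reaches a 6e-4 ratio)
  expect_lt(m$history$train_mse[200], 1e-2 * m$history$train_mse[1])
  expect_lt(m$history$train_mse[200], 0.9 * m$history$train_mse[100])
  # loss is non-increasing once smoothed over a 5-epoch window
  sm <- stats::filter(m$history$train_mse, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= pmax(1e-8, 0.05 * sm[-length(sm)])))
})

test_that("synthesis is deterministic and restores the input shape", {
  cfg <- unet_config(depth = 2, base_filters = 2, input_shape = c(16, 16),
                     epochs = 0, seed = 2)
  m <- build_model(cfg)
  se <- radiograph(matrix(runif(15 * 13, 0.2, 1), 15, 13))
  s1 <- synthesize(m, se)
  s2 <- synthesize(m, se)
  expect_identical(s1$pixels, s2$pixels)
  expect_identical(dim(s1$pixels), c(15L, 13L))
  expect_identical(s1$meta$kind, "synthesized_DES")
})

test_that("model serialization round trips", {
  m <- build_model(unet_config(depth = 2, base_filters = 2,
                               input_shape = c(16, 16), seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_synthesizer(m, path)
  m2 <- load_synthesizer(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
})
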