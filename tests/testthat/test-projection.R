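test_that("rotation matrix follows the stated elemental convention", {
  expect_equal(rotation_matrix(acquisition_angles(0, 0, 0)), diag(3))
  # Rx(90) maps the +y axis onto +z
  R <- rotation_matrix(acquisition_angles(90, 0, 0))
  expect_equal(as.numeric(R %*% c(0, 1, 0)), c(0, 0, 1), tolerance = 1e-12)
  # the printed Ry convention: +x maps toward +z under positive phi
  Ry <- rotation_matrix(acquisition_angles(0, 90, 0))
  expect_equal(as.numeric(Ry %*% c(1, 0, 0)), c(0, 0, 1), tolerance = 1e-12)
})

test_that("composite rotations are orthonormal with unit determinant", {
  set.seed(101)
  for (i in 1:25) {
    ang <- acquisition_angles(runif(1, 0, 35), runif(1, 0, 35),
                              runif(1, 0.1, 360))
    R <- rotation_matrix(ang)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_lt(abs(det(R) - 1), 1e-12)
  }
})

test_that("rotate_volume honours identity, round trips, and symmetry", {
  set.seed(7)
  mu <- array(runif(24^3), c(24, 24, 24))
  attr(mu, "spacing") <- c(1, 1, 1)
  expect_identical(rotate_volume(mu, diag(3)), mu)

  # 90 then -90 about x recovers the grid within interpolation tolerance
  Rp <- rotation_matrix(acquisition_angles(90, 0, 0))
  Rm <- rotation_matrix(acquisition_angles(-90, 0, 0))
  back <- rotate_volume(rotate_volume(mu, Rp), Rm)
  core <- 5:20 # ignore corners clipped by the rotation
  expect_lt(mean(abs(back[core, core, core] - mu[core, core, core])), 1e-3)

  # a centred, radially smooth ball is rotation invariant
  n <- 24
  ball <- array(0, c(n, n, n))
  ctr <- (n + 1) / 2
  for (k in 1:n) {
    d2 <- outer((1:n - ctr)^2, (1:n - ctr)^2, `+`) + (k - ctr)^2
    ball[, , k] <- 0.2 * exp(-d2 / (2 * 3^2))
  }
  attr(ball, "spacing") <- c(1, 1, 1)
  rb <- rotate_volume(ball, rotation_matrix(acquisition_angles(30, 12, 77)))
  expect_lt(mean(abs(rb - ball)), 1e-3)

  expect_error(rotate_volume(mu, matrix(1, 3, 3)), "orthonormal")
})

test_that("projection follows the Beer-Lambert closed form", {
  zero <- array(0, c(8, 8, 8))
  attr(zero, "spacing") <- c(1, 1, 1)
  expect_true(all(project(zero, I0 = 2)$pixels == 2))

  # uniform 0.1 /cm slab, 10 cm thick along the ray
  slab <- array(0.1, c(8, 100, 8))
  attr(slab, "spacing") <- c(1, 1, 1)
  img <- project(slab)
  expect_lt(max(abs(img$pixels - exp(-1))), 1e-6)

  # additivity: two stacked 5 cm slabs equal one 10 cm slab
  half <- array(0, c(8, 100, 8))
  half[, 1:50, ] <- 0.1
  half2 <- array(0, c(8, 100, 8))
  half2[, 51:100, ] <- 0.1
  attr(half, "spacing") <- attr(half2, "spacing") <- c(1, 1, 1)
  both <- half + half2
  attr(both, "spacing") <- c(1, 1, 1)
  expect_equal(project(both)$pixels, img$pixels, tolerance = 1e-12)

  expect_error(project(slab - 1), "non-negative")
})

test_that("adding material along a ray never raises intensity", {
  set.seed(11)
  mu <- array(runif(16^3, 0, 0.05), c(16, 16, 16))
  attr(mu, "spacing") <- c(2, 2, 2)
  base <- project(mu)$pixels
  mu2 <- mu
  mu2[8, , 8] <- mu2[8, , 8] + 0.1
  attr(mu2, "spacing") <- c(2, 2, 2)
  more <- project(mu2)$pixels
  expect_true(all(more <= base + 1e-15))
  expect_lt(more[8, 8], base[8, 8])
})

test_that("log-domain linearity: -ln(I/I0) equals the mu-pathlength sum", {
  cfg <- tiny_phantom_cfg()
  vol <- build_phantom(cfg, 1)
  specs <- cfg$energy_specs
  mu <- attenuation_volume(vol, specs$HE)
  img <- project(mu)
  # axis-aligned rays: the integral is exactly the voxel sum times the step
  L <- colSums(aperm(mu, c(2, 1, 3))) * cfg$spacing[2] / 10
  expect_equal(-log(img$pixels), t(L), tolerance = 1e-12)
})

test_that("projected feature position matches project_point", {
  # one attenuating voxel off-centre; after a gantry rotation the dark spot
  # must appear where project_point predicts
  n <- 33
  mu <- array(0, c(n, n, n))
  mu[25, 17, 21] <- 5
  attr(mu, "spacing") <- c(1, 1, 1)
  r_mm <- c(25 - (n + 1) / 2, 0, 21 - (n + 1) / 2)
  R <- rotation_matrix(acquisition_angles(0, 0, 90))
  img <- project(rotate_volume(mu, R))$pixels
  dark <- which(img == min(img), arr.ind = TRUE)
  pred <- project_point(r_mm, R, rep(n, 3), rep(1, 3))
  expect_lt(abs(dark[1, "row"] - pred[["y"]]), 1.5)
  expect_lt(abs(dark[1, "col"] - pred[["x"]]), 1.5)
})

test_that("radiograph container validates its inputs", {
  expect_error(radiograph(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
  expect_error(radiograph(matrix(1, 2, 2), pixel_spacing = 0), "positive")
  rg <- radiograph(matrix(1, 2, 2), kind = "DES")
  expect_identical(rg$meta$kind, "DES")
})
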