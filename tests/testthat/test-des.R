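test_that("des_subtract implements the weighted log subtraction", {
  he <- matrix(runif(16, 0.2, 1), 4, 4)
  le <- matrix(runif(16, 0.2, 1), 4, 4)
  # omega = 0 returns the HE image exactly
  expect_equal(des_subtract(he, le, omega = 0)$pixels, he, tolerance = 1e-15)
  # equal unit images with omega = 1: logs cancel to zero
  ones <- matrix(1, 4, 4)
  expect_equal(attr(des_subtract(ones, ones, omega = 1), "log_pixels"),
               matrix(0, 4, 4))
  # single-ray Beer-Lambert algebra: bone 0.3/0.6, soft 0.2/0.3, omega 0.5
  ihe <- matrix(exp(-(0.3 + 0.2)), 1, 1)
  ile <- matrix(exp(-(0.6 + 0.3)), 1, 1)
  ld <- attr(des_subtract(ihe, ile, omega = 0.5), "log_pixels")
  expect_equal(ld[1, 1], -0.05, tolerance = 1e-12)
  expect_equal(ld[1, 1], -(0.2 - 0.5 * 0.3), tolerance = 1e-12)
  expect_error(des_subtract(he, le[1:2, ]), "shape")
})

test_that("bone_cancel_weight is the bone HE/LE ratio", {
  specs <- default_energy_specs()
  expect_equal(bone_cancel_weight(specs$HE, specs$LE), 0.5)
  expect_equal(bone_cancel_weight(specs$HE, specs$HE), 1.0)
  mu <- specs$HE$mu
  mu_he <- mu; mu_he[c("rib", "spine")] <- 0.2
  mu_le <- mu; mu_le[c("rib", "spine")] <- 0.8
  expect_equal(bone_cancel_weight(energy_spec("HE", mu_he),
                                  energy_spec("LE", mu_le)), 0.25)
  mu_le[c("rib", "spine")] <- 0
  expect_error(bone_cancel_weight(energy_spec("HE", mu_he),
                                  energy_spec("LE", mu_le)), "positive")
})

test_that("bone cancellation: ribbed and bone-free phantoms give equal DES", {
  cfg <- tiny_phantom_cfg()
  specs <- cfg$energy_specs
  w <- bone_cancel_weight(specs$HE, specs$LE)
  vol <- build_phantom(cfg, 2)
  nb <- vol
  nb$labels[nb$labels %in% c(MATERIALS[["rib"]], MATERIALS[["spine"]])] <-
    MATERIALS[["air"]]
  R <- rotation_matrix(acquisition_angles(12, 12, 240))
  logdes <- function(v) {
    he <- project(rotate_volume(attenuation_volume(v, specs$HE), R))
    le <- project(rotate_volume(attenuation_volume(v, specs$LE), R))
    attr(des_subtract(he, le, omega = w), "log_pixels")
  }
  expect_lt(max(abs(logdes(vol) - logdes(nb))), 1e-6)
})

test_that("DES preserves soft-tissue (tumor) contrast", {
  cfg <- tiny_phantom_cfg()
  specs <- cfg$energy_specs
  w <- bone_cancel_weight(specs$HE, specs$LE)
  pair <- tiny_pair(cfg = cfg, omega = w)
  ld <- attr(pair$des, "log_pixels")
  gt <- project_point(tumor_centroid(build_phantom(cfg, 1)),
                      rotation_matrix(pair$provenance$angles),
                      cfg$shape, cfg$spacing)
  r0 <- round(gt[["y"]]); c0 <- round(gt[["x"]])
  tum <- ld[(r0 - 1):(r0 + 1), (c0 - 1):(c0 + 1)]
  ann <- ld[(r0 - 4):(r0 + 4), (c0 - 4):(c0 + 4)]
  contrast <- mean(tum) - (sum(ann) - sum(tum)) / (length(ann) - length(tum))
  expect_gt(abs(contrast), 1e-4)
})

test_that("augmentation is seeded, shape preserving, and pair-consistent", {
  pair <- tiny_pair()
  a1 <- augment_pair(pair, seed = 42)
  a2 <- augment_pair(pair, seed = 42)
  expect_identical(a1$se$pixels, a2$se$pixels)
  expect_identical(a1$des$pixels, a2$des$pixels)
  expect_identical(dim(a1$se$pixels), dim(pair$se$pixels))
  expect_identical(dim(a1$des$pixels), dim(pair$des$pixels))
  rec <- a1$provenance$augmentation
  expect_true(rec$type %in% c("scale", "crop"))
  if (rec$type == "scale") expect_true(rec$scale >= 0.8 && rec$scale <= 1.2)
  if (rec$type == "crop") expect_true(rec$crop_frac >= 0.5 && rec$crop_frac <= 1)
  # the same transform hits both members: zero masks must coincide
  expect_identical(a1$se$pixels == 0, a1$des$pixels == 0)
})

test_that("forced transforms behave as identity or zero-padded crop", {
  px <- matrix(runif(32 * 32, 0.1, 1), 32, 32)
  ident <- fluorodes:::apply_augmentation(px, list(type = "scale", scale = 1))
  expect_equal(ident, px, tolerance = 1e-12)
  rec <- list(type = "crop", crop_frac = 0.5,
              box = c(row = 5, col = 9, height = 16, width = 16))
  out <- fluorodes:::apply_augmentation(px, rec)
  expect_identical(dim(out), dim(px))
  expect_equal(out[5:20, 9:24], px[5:20, 9:24])
  # everything outside the crop box is exactly zero: 75% of the frame
  expect_equal(sum(out == 0), 32 * 32 - 16 * 16)
})

test_that("training grid enumeration matches the published protocol", {
  full <- enumerate_training_grid()
  expect_identical(nrow(full), 36000L)
  expect_true(all(full$theta == full$phi))
  expect_equal(sort(unique(full$gamma)), seq(3.6, 360, by = 3.6))
  expect_identical(sort(unique(full$phase)), 1:10)
  # deterministic order: phase-major, couch next, gantry fastest
  expect_true(all(diff(full$phase) >= 0))
  expect_equal(full$gamma[1:3], c(3.6, 7.2, 10.8))
  expect_equal(full$theta[1:200], rep(c(0, 1), each = 100))
  reduced <- enumerate_training_grid(gantry_deg = c(3.6, 7.2), couch_deg = 0,
                                     phases = 1:10)
  expect_identical(nrow(reduced), 20L)
})

test_that("generate_dataset writes pairs that regenerate from the manifest", {
  cfg <- tiny_phantom_cfg()
  grid <- enumerate_training_grid(gantry_deg = c(90, 180), couch_deg = 8,
                                  phases = c(1, 5))
  out_dir <- withr::local_tempdir()
  ds <- generate_dataset(cfg, grid, seed = 9, out_dir = out_dir)
  expect_length(ds$pairs, 4)
  expect_length(list.files(file.path(out_dir, "pairs"), pattern = "_se\\.pgm$"), 4)
  expect_length(list.files(file.path(out_dir, "pairs"), pattern = "_des\\.pgm$"), 4)
  expect_true(file.exists(file.path(out_dir, "manifest.csv")))
  man <- read.csv(file.path(out_dir, "manifest.csv"))
  expect_identical(nrow(man), 4L)

  # regeneration oracle: recompute one pair from its manifest row
  q <- 3
  base <- tiny_pair(phase = man$phase[q],
                    angles = acquisition_angles(man$theta[q], man$phi[q],
                                                man$gamma[q]),
                    cfg = cfg, omega = man$omega[q])
  rec <- ds$pairs[[q]]$provenance$augmentation
  expect_identical(rec$seed, man$aug_seed[q])
  redo <- augment_pair(base, rec$seed)
  expect_equal(redo$se$pixels, ds$pairs[[q]]$se$pixels, tolerance = 1e-12)
  expect_equal(redo$des$pixels, ds$pairs[[q]]$des$pixels, tolerance = 1e-12)
})
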