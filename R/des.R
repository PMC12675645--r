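# Dual-energy subtraction and training-set construction.
#
# The subtraction is the weighted logarithmic form
#   ln I_DES = ln I_HE - omega * ln I_LE,
# evaluated in the log domain and exponentiated back to the intensity domain.
# With omega equal to the bone HE/LE attenuation ratio the bone pathlength
# cancels exactly for noiseless parallel-beam projections, which is the
# central oracle of this module.

#' Weighted logarithmic dual-energy subtraction
#'
#' @param I_HE,I_LE high- and low-energy radiographs ([radiograph()] or plain
#'   matrices) of identical shape with positive intensities.
#' @param omega subtraction weight (default 0.5, the soft-tissue enhancing
#'   choice for 120/60 kVp).
#' @param floor intensities are floored at this value before taking logs
#'   (default 1e-8).
#' @return A [radiograph()] of kind `"DES"` (intensity domain,
#'   `I_HE * I_LE^-omega`); the log-domain array is kept in attribute
#'   `log_pixels` for metric use.
#' @export
des_subtract <- function(I_HE, I_LE, omega = 0.5, floor = 1e-8) {
  he <- as_pixels(I_HE); le <- as_pixels(I_LE)
  if (!all(dim(he) == dim(le))) stop("HE and LE images must have equal shape")
  if (any(he <= 0) || any(le <= 0)) {
    he <- pmax(he, floor); le <- pmax(le, floor)
    if (any(he <= 0) || any(le <= 0)) stop("non-positive pixels after flooring")
  }
  logdes <- log(he) - omega * log(le)
  meta <- if (inherits(I_HE, "radiograph")) I_HE$meta else list()
  out <- radiograph(exp(logdes),
                    pixel_spacing = if (inherits(I_HE, "radiograph"))
                      I_HE$pixel_spacing else 1,
                    energy = NA_character_, phase = meta$phase %||% NA_integer_,
                    angles = meta$angles, kind = "DES")
  attr(out, "log_pixels") <- logdes
  out
}

#' Exact bone-cancelling subtraction weight
#'
#' Returns `mu_HE(rib) / mu_LE(rib)`. With this weight the DES image is
#' independent of bone pathlength for noiseless parallel-beam projections.
#'
#' @param spec_HE,spec_LE [energy_spec()]s.
#' @return scalar weight.
#' @export
bone_cancel_weight <- function(spec_HE, spec_LE) {
  stopifnot(inherits(spec_HE, "energy_spec"), inherits(spec_LE, "energy_spec"))
  if (spec_LE$mu[["rib"]] <= 0) stop("LE bone attenuation must be positive")
  w <- spec_HE$mu[["rib"]] / spec_LE$mu[["rib"]]
  ws <- spec_HE$mu[["spine"]] / spec_LE$mu[["spine"]]
  if (abs(w - ws) > 1e-12)
    warning("rib and spine HE/LE ratios differ; cancellation is exact for rib only")
  w
}

#' Geometrically aligned (SE, DES) training pair
#'
#' @param se,des [radiograph()]s of identical shape (the SE member is the
#'   high-energy image).
#' @param provenance list carrying `phase`, `angles` and the augmentation
#'   record, if any.
#' @return An object of class `training_pair`.
#' @export
training_pair <- function(se, des, provenance = list()) {
  stopifnot(inherits(se, "radiograph"), inherits(des, "radiograph"))
  if (!all(dim(se$pixels) == dim(des$pixels)))
    stop("SE and DES members must have equal shape")
  structure(list(se = se, des = des, provenance = provenance),
            class = "training_pair")
}

#' Randomly scale or crop-and-pad a training pair
#'
#' One geometric transform is sampled and applied identically to both members:
#' either a scaling with factor in `[0.8, 1.2]` (the result is centre-cropped
#' or zero-padded back to the original shape) or a crop to 50-100% of the
#' original size at a uniform-random position, with the region outside the
#' crop zero-padded (original dimensions are always restored). The sampled
#' parameters are stored in `provenance$augmentation`.
#'
#' @param pair a [training_pair()].
#' @param seed integer seed; the same seed reproduces the transform exactly.
#' @return the augmented [training_pair()].
#' @export
augment_pair <- function(pair, seed) {
  stopifnot(inherits(pair, "training_pair"))
  h <- nrow(pair$se$pixels); w <- ncol(pair$se$pixels)
  rec <- with_seed(seed, {
    if (runif(1) < 0.5) {
      list(type = "scale", scale = runif(1, 0.8, 1.2), seed = seed)
    } else {
      f <- runif(1, 0.5, 1.0)
      ch <- max(1L, round(f * h)); cw <- max(1L, round(f * w))
      list(type = "crop", crop_frac = f,
           box = c(row = sample.int(h - ch + 1L, 1), col = sample.int(w - cw + 1L, 1),
                   height = ch, width = cw),
           seed = seed)
    }
  })
  tf <- function(px) apply_augmentation(px, rec)
  se <- pair$se; des <- pair$des
  se$pixels <- tf(se$pixels); des$pixels <- tf(des$pixels)
  prov <- pair$provenance
  prov$augmentation <- rec
  training_pair(se, des, prov)
}

apply_augmentation <- function(px, rec) {
  h <- nrow(px); w <- ncol(px)
  if (rec$type == "scale") {
    h2 <- max(1L, round(rec$scale * h)); w2 <- max(1L, round(rec$scale * w))
    sc <- .resize_bilinear_cpp(px, h2, w2)
    out <- matrix(0, h, w)
    if (h2 >= h) { # centre crop back
      r0 <- floor((h2 - h) / 2); c0 <- floor((w2 - w) / 2)
      out <- sc[r0 + seq_len(h), c0 + seq_len(w), drop = FALSE]
    } else {       # centre zero-pad back
      r0 <- floor((h - h2) / 2); c0 <- floor((w - w2) / 2)
      out[r0 + seq_len(h2), c0 + seq_len(w2)] <- sc
    }
    out
  } else {
    b <- rec$box
    out <- matrix(0, h, w)
    rows <- b[["row"]] + seq_len(b[["height"]]) - 1L
    cols <- b[["col"]] + seq_len(b[["width"]]) - 1L
    out[rows, cols] <- px[rows, cols]
    out
  }
}

#' Enumerate the (phase, couch, gantry) training grid
#'
#' The full grid is 10 respiratory phases x 36 couch-angle pairs
#' `(0,0), (1,1), ..., (35,35)` x 100 gantry angles `3.6, 7.2, ..., 360`
#' degrees = 36,000 entries. Order is deterministic: phase-major, then couch,
#' then gantry (gantry fastest).
#'
#' @param gantry_deg gantry angles in degrees.
#' @param couch_deg couch angles; each value `a` yields the pair
#'   `(theta, phi) = (a, a)`.
#' @param phases respiratory phase indices.
#' @return data.frame with columns `phase`, `theta`, `phi`, `gamma`.
#' @export
enumerate_training_grid <- function(gantry_deg = seq(3.6, 360, by = 3.6),
                                    couch_deg = 0:35, phases = 1:10) {
  grid <- expand.grid(gamma = gantry_deg, couch = couch_deg, phase = phases,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(phase = grid$phase, theta = grid$couch, phi = grid$couch,
             gamma = grid$gamma)
}

#' Generate an (SE, DES) training dataset from the phantom
#'
#' For every grid entry: build the phantom phase, attenuate at both energies,
#' rotate, project, subtract with weight `omega`, and (optionally) augment.
#' Phantom volumes and their projections are cached per (phase, angles)
#' combination encountered.
#'
#' @param config a [phantom_config()].
#' @param grid data.frame from [enumerate_training_grid()].
#' @param omega subtraction weight (default 0.5).
#' @param augment apply [augment_pair()] to every pair (default TRUE).
#' @param seed master seed; per-pair augmentation seeds are derived from it.
#' @param out_dir if non-NULL, write `pairs/NNNNNN_{se,des}.pgm` (16-bit,
#'   max-normalized) plus `manifest.csv` there.
#' @param detector_shape optional `(rows, cols)`; projections are bilinearly
#'   resampled to this detector size (default: native grid resolution).
#' @param bin average `bin x bin` blocks of projected rays per detector
#'   pixel (default 1). Pass the phantom config at a correspondingly finer
#'   grid; binning removes voxelization aliasing from the images.
#' @return invisible list with `pairs` (list of [training_pair()]) and
#'   `manifest` (data.frame).
#' @export
generate_dataset <- function(config, grid, omega = 0.5, augment = TRUE,
                             seed = 1L, out_dir = NULL,
                             detector_shape = NULL, bin = 1L) {
  stopifnot(inherits(config, "phantom_config"), nrow(grid) >= 1)
  specs <- config$energy_specs
  mu_cache <- list()
  get_mu <- function(phase) {
    key <- as.character(phase)
    if (is.null(mu_cache[[key]])) {
      vol <- build_phantom(config, phase)
      mu_cache[[key]] <<- list(HE = attenuation_volume(vol, specs$HE),
                               LE = attenuation_volume(vol, specs$LE))
    }
    mu_cache[[key]]
  }
  pairs <- vector("list", nrow(grid))
  man <- grid
  man$omega <- omega
  man$aug_type <- NA_character_
  man$aug_param <- NA_real_
  man$aug_seed <- NA_integer_
  for (q in seq_len(nrow(grid))) {
    mu <- get_mu(grid$phase[q])
    ang <- acquisition_angles(grid$theta[q], grid$phi[q], grid$gamma[q])
    R <- rotation_matrix(ang)
    meta <- list(phase = grid$phase[q], angles = ang)
    he <- project(rotate_volume(mu$HE, R),
                  meta = c(meta, list(energy = "HE", kind = "SE")))
    le <- project(rotate_volume(mu$LE, R),
                  meta = c(meta, list(energy = "LE", kind = "LE")))
    if (bin > 1L) {
      bin_rg <- function(rg) {
        rg$pixels <- bin_pixels(rg$pixels, bin)
        rg$pixel_spacing <- rg$pixel_spacing * bin
        rg
      }
      he <- bin_rg(he); le <- bin_rg(le)
    }
    if (!is.null(detector_shape)) {
      resize_rg <- function(rg) {
        sc <- dim(rg$pixels) / detector_shape
        rg$pixel_spacing <- rg$pixel_spacing * sc
        rg$pixels <- .resize_bilinear_cpp(rg$pixels, detector_shape[1],
                                          detector_shape[2])
        rg
      }
      he <- resize_rg(he); le <- resize_rg(le)
    }
    des <- des_subtract(he, le, omega = omega)
    pair <- training_pair(he, des,
                          provenance = list(phase = grid$phase[q], angles = ang,
                                            omega = omega))
    if (augment) {
      aug_seed <- derive_seed(seed, paste0("augment-", q))
      pair <- augment_pair(pair, aug_seed)
      rec <- pair$provenance$augmentation
      man$aug_type[q] <- rec$type
      man$aug_param[q] <- if (rec$type == "scale") rec$scale else rec$crop_frac
      man$aug_seed[q] <- aug_seed
    }
    pairs[[q]] <- pair
  }
  if (!is.null(out_dir)) {
    pair_dir <- file.path(out_dir, "pairs")
    dir.create(pair_dir, recursive = TRUE, showWarnings = FALSE)
    ok <- FALSE
    on.exit(if (!ok) unlink(out_dir, recursive = TRUE), add = TRUE)
    for (q in seq_along(pairs)) {
      write_radiograph(pairs[[q]]$se,
                       file.path(pair_dir, sprintf("%06d_se.pgm", q)),
                       bits = 16L)
      write_radiograph(pairs[[q]]$des,
                       file.path(pair_dir, sprintf("%06d_des.pgm", q)),
                       bits = 16L)
    }
    write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    ok <- TRUE
  }
  invisible(list(pairs = pairs, manifest = man))
}
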