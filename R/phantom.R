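# 4D dual-energy digital thorax phantom.
#
# The phantom stands in for a licensed 4D anthropomorphic CT phantom: an
# ellipsoidal soft-tissue torso, two ellipsoidal lungs, a posterior spinal
# column, parametric curved rib arcs, and a spherical tumor that translates
# superior-inferior with the respiratory phase. All solids are analytic and
# rasterized onto the voxel grid, so volumes are bit-reproducible.

#' Material codes used by the phantom
#'
#' Integer labels for the six materials of the digital thorax phantom.
#'
#' @format Named integer vector.
#' @export
MATERIALS <- c(air = 0L, soft_tissue = 1L, lung = 2L, rib = 3L,
               spine = 4L, tumor = 5L)

#' Energy specification: linear attenuation per material
#'
#' Maps each material code to a linear attenuation coefficient (1/cm) at one
#' effective energy. Air must have exactly zero attenuation and no material
#' may attenuate more at high energy than at low energy.
#'
#' @param energy_name `"HE"` or `"LE"`.
#' @param mu named numeric vector over the names of [MATERIALS] (1/cm).
#' @return An object of class `energy_spec`.
#' @export
energy_spec <- function(energy_name, mu) {
  stopifnot(energy_name %in% c("HE", "LE"))
  if (!all(names(MATERIALS) %in% names(mu)))
    stop("mu must name every material: ",
         paste(setdiff(names(MATERIALS), names(mu)), collapse = ", "))
  mu <- mu[names(MATERIALS)]
  if (mu[["air"]] != 0) stop("mu(air) must be exactly 0")
  if (any(mu < 0)) stop("attenuation coefficients must be non-negative")
  structure(list(energy_name = energy_name, mu = mu), class = "energy_spec")
}

#' Default high/low-energy attenuation specifications
#'
#' Effective monoenergetic surrogates for 120 kVp (HE) and 60 kVp (LE) beams.
#' Bone (rib and spine) is constructed with an HE/LE ratio of exactly 0.5, so
#' that a subtraction weight of 0.5 is the exact bone-cancelling weight.
#'
#' @return List with elements `HE` and `LE`, each an [energy_spec()].
#' @export
default_energy_specs <- function() {
  he <- c(air = 0, soft_tissue = 0.18, lung = 0.04, rib = 0.30,
          spine = 0.30, tumor = 0.19)
  le <- c(air = 0, soft_tissue = 0.25, lung = 0.06, rib = 0.60,
          spine = 0.60, tumor = 0.27)
  list(HE = energy_spec("HE", he), LE = energy_spec("LE", le))
}

#' Cortical-bone energy specifications
#'
#' Like [default_energy_specs()] but with rib and spine at cortical-bone
#' attenuation (0.48/0.96 per cm), the regime of clinical chest imaging where
#' rib shadows are strong enough to disrupt template tracking. The HE/LE bone
#' ratio remains exactly 0.5.
#'
#' @return List with elements `HE` and `LE`, each an [energy_spec()].
#' @export
cortical_energy_specs <- function() {
  he <- c(air = 0, soft_tissue = 0.18, lung = 0.04, rib = 0.48,
          spine = 0.48, tumor = 0.19)
  le <- c(air = 0, soft_tissue = 0.25, lung = 0.06, rib = 0.96,
          spine = 0.96, tumor = 0.27)
  list(HE = energy_spec("HE", he), LE = energy_spec("LE", le))
}

#' Configure the digital thorax phantom
#'
#' Geometry defaults scale with the grid extent so the same anatomy fits any
#' grid; the tumor diameter and breathing amplitude are absolute (mm), as they
#' are physical quantities. Phase 1 is the full-exhale reference; the tumor
#' translates inferiorly by `amplitude * sin^2(pi * (p - 1) / phase_count)`.
#'
#' @param shape integer length-3 grid dimensions `(nx, ny, nz)`; x is
#'   patient-left, y is posterior, z is superior.
#' @param spacing voxel size in mm (scalar or length 3).
#' @param tumor_center tumor centre in centred mm coordinates at phase 1;
#'   default places it mid-height in the right lung.
#' @param tumor_diameter tumor diameter in mm (default 10).
#' @param amplitude superior-inferior breathing amplitude in mm (default 10).
#' @param phase_count number of respiratory phases (default 10).
#' @param rib_count rib arcs per side (default 10, valid 8-12).
#' @param energy_specs list with `HE` and `LE` [energy_spec()]s.
#' @param ... overrides for the derived geometry fields (`torso_semiaxes`,
#'   `lung_centers`, `lung_semiaxes`, `spine_center`, `spine_radius`,
#'   `rib_ellipse`, `rib_tube_radius`, `rib_z_range`, `rib_slope`).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(160L, 160L, 160L), spacing = 1,
                           tumor_center = NULL, tumor_diameter = 10,
                           amplitude = 10, phase_count = 10L,
                           rib_count = 10L,
                           energy_specs = default_energy_specs(), ...) {
  shape <- as.integer(shape)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(shape <= 0) || any(spacing <= 0))
    stop("grid shape and spacing must be positive")
  if (tumor_diameter <= 0) stop("tumor diameter must be positive")
  if (phase_count < 1) stop("phase_count must be >= 1")
  if (rib_count < 8 || rib_count > 12) stop("rib_count must be in 8..12")
  half <- shape * spacing / 2 # half extents, mm
  cfg <- list(
    shape = shape, spacing = spacing,
    torso_semiaxes = c(0.88, 0.72) * half[1:2],
    lung_centers = rbind(right = c(-0.42 * half[1], -0.06 * half[2], 0.05 * half[3]),
                         left  = c( 0.42 * half[1], -0.06 * half[2], 0.05 * half[3])),
    lung_semiaxes = c(0.30 * half[1], 0.50 * half[2], 0.62 * half[3]),
    spine_center = c(0, 0.58 * half[2]),
    spine_radius = 0.10 * half[1],
    rib_ellipse = c(0.80 * half[1], 0.62 * half[2]),
    rib_tube_radius = max(0.022 * half[3], 1.5 * min(spacing)),
    rib_z_range = c(-0.75, 0.85) * half[3],
    rib_slope = -0.18 * half[3],
    rib_count = as.integer(rib_count),
    tumor_diameter = tumor_diameter,
    amplitude = amplitude,
    phase_count = as.integer(phase_count),
    energy_specs = energy_specs
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown phantom_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg$tumor_center <- tumor_center %||%
    (cfg$lung_centers["right", ] + c(0, 0, -0.35 * cfg$lung_semiaxes[3]))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

# tumor displacement (mm, inferior) at phase p
tumor_displacement <- function(config, phase) {
  config$amplitude * sin(pi * (phase - 1) / config$phase_count)^2
}

#' Tumor centre at a given phase (centred mm coordinates)
#' @param config a [phantom_config()].
#' @param phase respiratory phase in `1..phase_count`.
#' @return length-3 numeric (x, y, z) mm.
#' @export
tumor_center_at_phase <- function(config, phase) {
  config$tumor_center - c(0, 0, tumor_displacement(config, phase))
}

validate_phantom_config <- function(cfg) {
  r <- cfg$tumor_diameter / 2
  for (p in seq_len(cfg$phase_count)) {
    ctr <- tumor_center_at_phase(cfg, p)
    inside <- FALSE
    for (l in seq_len(nrow(cfg$lung_centers))) {
      d <- (ctr - cfg$lung_centers[l, ]) / (cfg$lung_semiaxes - r)
      if (all(cfg$lung_semiaxes > r) && sum(d^2) <= 1) inside <- TRUE
    }
    if (!inside)
      stop("tumor (with its full sphere) leaves the lung at phase ", p,
           "; reduce amplitude or move tumor_center")
  }
  invisible(cfg)
}

#' Build one respiratory phase of the phantom
#'
#' Rasterizes the analytic anatomy onto the voxel grid. Deterministic: a fixed
#' config and phase always produce bit-identical volumes.
#'
#' @param config a [phantom_config()].
#' @param phase respiratory phase in `1..phase_count`.
#' @return A `material_volume`: list with integer array `labels` (material
#'   code per voxel), `spacing` (mm) and `phase`.
#' @export
build_phantom <- function(config, phase) {
  stopifnot(inherits(config, "phantom_config"))
  if (phase < 1 || phase > config$phase_count)
    stop("phase must be in 1..", config$phase_count)
  n <- config$shape; sp <- config$spacing
  x <- (seq_len(n[1]) - (n[1] + 1) / 2) * sp[1]
  y <- (seq_len(n[2]) - (n[2] + 1) / 2) * sp[2]
  z <- (seq_len(n[3]) - (n[3] + 1) / 2) * sp[3]

  labels <- array(MATERIALS[["air"]], dim = n)

  torso2d <- outer((x / config$torso_semiaxes[1])^2,
                   (y / config$torso_semiaxes[2])^2, `+`) <= 1
  spine2d <- outer((x - config$spine_center[1])^2,
                   (y - config$spine_center[2])^2, `+`) <=
    config$spine_radius^2
  spine2d <- spine2d & torso2d

  lungq <- lapply(seq_len(nrow(config$lung_centers)), function(l) {
    c0 <- config$lung_centers[l, ]
    outer(((x - c0[1]) / config$lung_semiaxes[1])^2,
          ((y - c0[2]) / config$lung_semiaxes[2])^2, `+`)
  })
  lungz <- lapply(seq_len(nrow(config$lung_centers)), function(l) {
    ((z - config$lung_centers[l, 3]) / config$lung_semiaxes[3])^2
  })

  tc <- tumor_center_at_phase(config, phase)
  tr <- config$tumor_diameter / 2
  tum2d <- outer((x - tc[1])^2, (y - tc[2])^2, `+`)

  for (k in seq_len(n[3])) {
    sl <- labels[, , k]
    sl[torso2d] <- MATERIALS[["soft_tissue"]]
    for (l in seq_along(lungq)) {
      m <- (lungq[[l]] + lungz[[l]][k]) <= 1
      sl[m] <- MATERIALS[["lung"]]
    }
    sl[spine2d & sl == MATERIALS[["soft_tissue"]]] <- MATERIALS[["spine"]]
    tm <- (tum2d + (z[k] - tc[3])^2) <= tr^2
    sl[tm & sl == MATERIALS[["lung"]]] <- MATERIALS[["tumor"]]
    labels[, , k] <- sl
  }

  labels <- rasterize_ribs(labels, config, x, y, z)

  vol <- structure(list(labels = labels, spacing = sp, phase = as.integer(phase)),
                   class = "material_volume")
  if (!any(vol$labels == MATERIALS[["tumor"]]))
    stop("tumor rasterized to zero voxels; grid too coarse for the configured diameter")
  vol
}

# Curved rib arcs: per side, rib_count arcs following an axial ellipse from
# the para-spinal region around to the front, drifting inferiorly (rib_slope)
# from back to front. Voxels within rib_tube_radius of the sampled curve and
# currently soft tissue become rib.
rasterize_ribs <- function(labels, config, x, y, z) {
  n <- dim(labels); sp <- config$spacing
  ex <- config$rib_ellipse[1]; ey <- config$rib_ellipse[2]
  zs <- seq(config$rib_z_range[1], config$rib_z_range[2],
            length.out = config$rib_count)
  rr <- config$rib_tube_radius
  # ball offsets in voxel units
  off <- expand.grid(dx = seq(-ceiling(rr / sp[1]), ceiling(rr / sp[1])),
                     dy = seq(-ceiling(rr / sp[2]), ceiling(rr / sp[2])),
                     dz = seq(-ceiling(rr / sp[3]), ceiling(rr / sp[3])))
  keep <- (off$dx * sp[1])^2 + (off$dy * sp[2])^2 + (off$dz * sp[3])^2 <= rr^2
  off <- off[keep, ]
  ts <- seq(0, 1, length.out = 200) # curve samples, back to front
  soft <- MATERIALS[["soft_tissue"]]
  for (side in c(-1, 1)) {
    # polar angle: from near the spine (posterior) sweeping to anterior
    ang <- (0.5 - 0.92 * ts) * pi      # pi/2 (posterior) -> ~ -0.42 pi (anterior)
    for (rz in zs) {
      cx <- side * ex * cos(ang)
      cy <- ey * sin(ang)
      cz <- rz + config$rib_slope * ts
      i <- round(cx / sp[1] + (n[1] + 1) / 2)
      j <- round(cy / sp[2] + (n[2] + 1) / 2)
      k <- round(cz / sp[3] + (n[3] + 1) / 2)
      for (q in seq_len(nrow(off))) {
        ii <- i + off$dx[q]; jj <- j + off$dy[q]; kk <- k + off$dz[q]
        ok <- ii >= 1 & ii <= n[1] & jj >= 1 & jj <= n[2] & kk >= 1 & kk <= n[3]
        if (!any(ok)) next
        lin <- ii[ok] + n[1] * (jj[ok] - 1 + n[2] * (kk[ok] - 1))
        lin <- lin[labels[lin] == soft]
        labels[lin] <- MATERIALS[["rib"]]
      }
    }
  }
  labels
}

#' Convert a material volume to a linear-attenuation volume
#'
#' Element-wise lookup of the attenuation coefficient (1/cm) of each voxel's
#' material at the given energy. Air maps to exactly 0.
#'
#' @param vol a `material_volume` from [build_phantom()].
#' @param spec an [energy_spec()].
#' @return numeric array of attenuation coefficients with `spacing` attribute.
#' @export
attenuation_volume <- function(vol, spec) {
  stopifnot(inherits(vol, "material_volume"), inherits(spec, "energy_spec"))
  codes <- sort(unique(as.vector(vol$labels)))
  unknown <- setdiff(codes, MATERIALS)
  if (length(unknown))
    stop("unknown material label(s): ", paste(unknown, collapse = ", "))
  lut <- numeric(max(MATERIALS) + 1)
  lut[MATERIALS + 1] <- spec$mu[names(MATERIALS)]
  mu <- array(lut[vol$labels + 1L], dim = dim(vol$labels))
  attr(mu, "spacing") <- vol$spacing
  mu
}

#' Tumor voxel centroid in centred mm coordinates
#' @param vol a `material_volume`.
#' @return length-3 numeric (x, y, z) mm.
#' @export
tumor_centroid <- function(vol) {
  idx <- which(vol$labels == MATERIALS[["tumor"]], arr.ind = TRUE)
  if (nrow(idx) == 0) stop("volume contains no tumor voxels")
  n <- dim(vol$labels)
  colMeans((idx - rep((n + 1) / 2, each = nrow(idx))) *
             rep(vol$spacing, each = nrow(idx)))
}

#' @export
print.material_volume <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = MATERIALS,
                      labels = names(MATERIALS)))
  cat("<material_volume> ", paste(dim(x$labels), collapse = "x"),
      " voxels @ ", paste(signif(x$spacing, 3), collapse = "x"),
      " mm, phase ", x$phase, "\n", sep = "")
  print(tab)
  invisible(x)
}
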