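# Shared fixtures: everything is generated in code at test time.

# small thorax phantom: 32^3 voxels at 8 mm keeps the full anatomy (256 mm
# field of view) while building in well under a second; the tumor is enlarged
# to 20 mm so the sphere always rasterizes on the coarse grid
tiny_phantom_cfg <- function(tumor_diameter = 20, ...) {
  phantom_config(shape = c(32L, 32L, 32L), spacing = 8,
                 tumor_diameter = tumor_diameter, ...)
}

# desk-scale phantom used by the heavier end-to-end tests
desk_phantom_cfg <- function(...) {
  phantom_config(shape = c(64L, 64L, 64L), spacing = 4, ...)
}

# deterministic structured test image: a smooth gradient plus a bright blob,
# enough texture for registration and histogram tests
blob_image <- function(n = 64, cx = n / 2, cy = n / 2, r = n / 8) {
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  base <- 0.2 + 0.4 * (xs + ys) / (2 * n)
  blob <- exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * r^2))
  base + 0.4 * blob
}

# DES/SE pair fixture from the tiny phantom at one angle
tiny_pair <- function(phase = 1, angles = acquisition_angles(0, 0, 180),
                      cfg = tiny_phantom_cfg(), omega = 0.5) {
  specs <- cfg$energy_specs
  vol <- build_phantom(cfg, phase)
  R <- rotation_matrix(angles)
  he <- project(rotate_volume(attenuation_volume(vol, specs$HE), R),
                meta = list(energy = "HE", phase = phase, angles = angles,
                            kind = "SE"))
  le <- project(rotate_volume(attenuation_volume(vol, specs$LE), R),
                meta = list(energy = "LE", phase = phase, angles = angles,
                            kind = "LE"))
  training_pair(he, des_subtract(he, le, omega = omega),
                provenance = list(phase = phase, angles = angles,
                                  omega = omega))
}

# brute-force NCC argmax over every admissible template position in a frame,
# with the same row-major first-maximum tie-break as the tracker
brute_force_match <- function(frame, patch) {
  th <- nrow(patch); tw <- ncol(patch)
  best <- -2; br <- 1; bc <- 1
  te <- sqrt(sum(patch^2))
  for (r in seq_len(nrow(frame) - th + 1)) {
    for (c in seq_len(ncol(frame) - tw + 1)) {
      win <- frame[r:(r + th - 1), c:(c + tw - 1)]
      s <- sum(win * patch) / (sqrt(sum(win^2)) * te)
      if (s > best) { best <- s; br <- r; bc <- c }
    }
  }
  c(row = br, col = bc, score = best)
}

# single connected component check (6-connectivity) for a logical 3D mask
is_connected3d <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  n <- dim(mask)
  lin <- function(i) i[, 1] + n[1] * (i[, 2] - 1 + n[2] * (i[, 3] - 1))
  all_lin <- lin(idx)
  seen <- rep(FALSE, length(all_lin))
  names(seen) <- all_lin
  queue <- all_lin[1]
  seen[as.character(queue)] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  coords <- idx
  rownames(coords) <- as.character(all_lin)
  while (length(queue)) {
    cur <- coords[as.character(queue[1]), , drop = FALSE]
    queue <- queue[-1]
    for (q in seq_len(6)) {
      nb <- cur + offs[q, , drop = FALSE]
      if (any(nb < 1) || any(nb > n)) next
      key <- as.character(nb[, 1] + n[1] * (nb[, 2] - 1 + n[2] * (nb[, 3] - 1)))
      if (!is.na(seen[key]) && !seen[key]) {
        seen[key] <- TRUE
        queue <- c(queue, as.numeric(key))
      }
    }
  }
  all(seen)
}
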