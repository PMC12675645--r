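# Volume rotation and digitally reconstructed radiographs (DRRs).
#
# Convention: the volume axes are x (patient-left), y (posterior), z
# (superior). Rays travel along +y (parallel beam), so the detector plane is
# (x, z): image rows index z, columns index x. The rotation is applied to
# coordinates about the volume centre, V_rot(r) = V(R r), with
# R = Rx(theta) Ry(phi) Rz(gamma) composed from the elemental matrices below.

#' Acquisition angles (couch and gantry)
#'
#' @param theta,phi couch angles in degrees (the training grid uses pairs with
#'   `theta == phi` in `[0, 35]`).
#' @param gamma gantry angle in degrees, in `(0, 360]` for the training grid.
#' @return An object of class `acquisition_angles`.
#' @export
acquisition_angles <- function(theta = 0, phi = 0, gamma = 0) {
  stopifnot(is.finite(theta), is.finite(phi), is.finite(gamma))
  structure(list(theta = theta, phi = phi, gamma = gamma),
            class = "acquisition_angles")
}

#' Composite rotation matrix Rx(theta) Ry(phi) Rz(gamma)
#'
#' The elemental matrices follow the published convention of this workflow
#' literally (note `Ry` carries `-sin(phi)` at position (1,3), the transpose
#' of the more common right-handed form; the stray symbol printed in `Rz` at
#' position (3,2) is treated as a typographical 0). The result is always a
#' proper rotation: orthonormal with determinant +1.
#'
#' @param angles an [acquisition_angles()] (degrees).
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angles) {
  stopifnot(inherits(angles, "acquisition_angles"))
  t_ <- angles$theta * pi / 180
  p_ <- angles$phi * pi / 180
  g_ <- angles$gamma * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(t_), -sin(t_),
                 0, sin(t_), cos(t_)), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(p_), 0, -sin(p_),
                 0, 1, 0,
                 sin(p_), 0, cos(p_)), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(g_), -sin(g_), 0,
                 sin(g_), cos(g_), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  Rx %*% Ry %*% Rz
}

is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Rotate an attenuation volume about its centre
#'
#' Trilinear resampling; voxels sampled from outside the field are air (0).
#' The identity rotation returns the input unchanged.
#'
#' @param mu_grid 3D numeric array with a `spacing` attribute (mm), e.g. from
#'   [attenuation_volume()].
#' @param R 3x3 orthonormal rotation matrix with det +1.
#' @return rotated array, same shape and `spacing`.
#' @export
rotate_volume <- function(mu_grid, R) {
  if (!is_rotation(R))
    stop("R must be orthonormal with determinant +1")
  spacing <- attr(mu_grid, "spacing") %||% rep(1, 3)
  if (max(abs(R - diag(3))) < 1e-14) return(mu_grid)
  out <- .rotate_volume_cpp(mu_grid, dim(mu_grid), R, spacing)
  attr(out, "spacing") <- spacing
  out
}

#' 2D radiograph container
#'
#' @param pixels numeric matrix of non-negative intensities (rows = z,
#'   superior-inferior; columns = x, left-right).
#' @param pixel_spacing mm per pixel, length 2 `(row, col)` or scalar.
#' @param energy,phase,angles,kind metadata; `kind` is one of
#'   `"SE"`, `"HE"`, `"LE"`, `"DES"`, `"synthesized_DES"`.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, pixel_spacing = 1, energy = NA_character_,
                       phase = NA_integer_, angles = NULL, kind = "SE") {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (any(pixel_spacing <= 0)) stop("pixel spacing must be positive")
  kind <- match.arg(kind, c("SE", "HE", "LE", "DES", "synthesized_DES"))
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 meta = list(energy = energy, phase = phase,
                             angles = angles, kind = kind)),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat("<radiograph> ", nrow(x$pixels), "x", ncol(x$pixels), " px @ ",
      paste(signif(x$pixel_spacing, 3), collapse = "x"), " mm, kind ",
      x$meta$kind, "\n", sep = "")
  invisible(x)
}

as_pixels <- function(img) {
  if (inherits(img, "radiograph")) img$pixels else as.matrix(img)
}

#' Parallel-beam forward projection (DRR)
#'
#' Beer-Lambert ray integration along +y: per detector pixel the intensity is
#' `I0 * exp(-integral of mu dl)` with the line integral taken as the Riemann
#' sum of voxel attenuations times the step (one voxel) along the ray. No
#' noise or scatter is simulated.
#'
#' @param mu_grid 3D array of linear attenuation (1/cm) with `spacing`
#'   attribute in mm.
#' @param I0 incident intensity (default 1).
#' @param meta optional list (`energy`, `phase`, `angles`, `kind`) copied to
#'   the output.
#' @return A [radiograph()] with pixel values in `(0, I0]`.
#' @export
project <- function(mu_grid, I0 = 1.0, meta = list()) {
  if (any(mu_grid < 0)) stop("attenuation must be non-negative")
  spacing <- attr(mu_grid, "spacing") %||% rep(1, 3)
  # path integral: sum over y of mu (1/cm) * dy (cm)
  L <- colSums(aperm(mu_grid, c(2, 1, 3))) * spacing[2] / 10
  pixels <- t(I0 * exp(-L)) # rows = z, cols = x
  radiograph(pixels, pixel_spacing = c(spacing[3], spacing[1]),
             energy = meta$energy %||% NA_character_,
             phase = meta$phase %||% NA_integer_,
             angles = meta$angles,
             kind = meta$kind %||% "SE")
}

#' Project a centred mm coordinate onto the detector
#'
#' A feature at centred coordinate `r` (mm) in the unrotated volume appears,
#' after [rotate_volume()] with matrix `R` and [project()], at the detector
#' position returned here (units: px, `(x = col, y = row)`, 1-based).
#'
#' @param r length-3 numeric, centred mm coordinates.
#' @param R 3x3 rotation matrix used for the volume.
#' @param shape volume grid dimensions.
#' @param spacing voxel spacing (mm).
#' @return named numeric `(x, y)` in pixels (continuous).
#' @export
project_point <- function(r, R, shape, spacing) {
  c_out <- crossprod(R, r) # R^T r: output coords of the rotated feature
  x_px <- c_out[1] / spacing[1] + (shape[1] + 1) / 2
  y_px <- c_out[3] / spacing[3] + (shape[3] + 1) / 2
  c(x = x_px, y = y_px)
}
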