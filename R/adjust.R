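# Treatment-session image adjustment: bring clinical-style fluoroscopy frames
# into the DRR-like appearance domain the synthesizer was trained on.
# Order fixed by the workflow: affine registration (computed once against the
# first frame), histogram matching to the reference DRR, 5x5 median smoothing.

#' 2D affine transform (translation, rotation, isotropic scale)
#'
#' Maps reference (DRR) pixel coordinates to frame coordinates:
#' `p_frame = scale * Rot(rotation) * (p_ref - centre) + centre + translation`
#' with `p = (col, row)` and rotation in degrees, counter-clockwise.
#'
#' @param tx,ty translation in pixels.
#' @param rotation rotation in degrees.
#' @param scale isotropic scale factor (> 0).
#' @return An object of class `affine_transform2d`.
#' @export
affine_transform2d <- function(tx = 0, ty = 0, rotation = 0, scale = 1) {
  if (scale <= 0) stop("scale must be positive")
  structure(list(tx = tx, ty = ty, rotation = rotation, scale = scale),
            class = "affine_transform2d")
}

#' @export
print.affine_transform2d <- function(x, ...) {
  cat(sprintf("<affine_transform2d> t = (%.3f, %.3f) px, rot = %.3f deg, scale = %.4f\n",
              x$tx, x$ty, x$rotation, x$scale))
  invisible(x)
}

#' Resample an image through an affine transform
#'
#' Pulls `img` into the reference geometry: the output at reference pixel `p`
#' is `img` sampled (bilinearly) at the transformed location. With the
#' transform returned by [affine_register()] this maps a fluoroscopy frame
#' into the geometry of the reference DRR.
#'
#' @param img matrix or [radiograph()].
#' @param tf an [affine_transform2d()].
#' @return matrix of the same shape.
#' @export
apply_affine <- function(img, tf) {
  stopifnot(inherits(tf, "affine_transform2d"))
  .warp_affine2d_cpp(as_pixels(img), tf$tx, tf$ty, tf$rotation, tf$scale)
}

# Pearson correlation of the warped frame against the reference, restricted
# to an interior crop (15% margin) and to pixels whose warp stays fully
# inside the frame. The crop matters: blending against the zero fill at the
# borders creates spurious local maxima at integer shifts that trap the
# refinement stage.
warp_similarity <- function(par, target, frame) {
  w <- .warp_affine2d_cpp(frame, par[1], par[2], par[3], par[4])
  wm <- .warp_affine2d_cpp(matrix(1, nrow(frame), ncol(frame)),
                           par[1], par[2], par[3], par[4])
  mr <- ceiling(0.15 * dim(frame))
  ri <- (mr[1] + 1):(nrow(frame) - mr[1])
  ci <- (mr[2] + 1):(ncol(frame) - mr[2])
  v1 <- as.numeric(w[ri, ci])
  v2 <- as.numeric(target[ri, ci])
  keep <- as.numeric(wm[ri, ci]) > 0.999
  if (sum(keep) < 16) return(-1)
  s <- suppressWarnings(stats::cor(v1[keep], v2[keep]))
  if (!is.finite(s)) -1 else s
}

#' Affine registration of a reference DRR to a fluoroscopy frame
#'
#' Estimates translation, rotation and isotropic scale by maximizing a
#' normalized-correlation similarity with a coarse translation search
#' followed by Nelder-Mead refinement over all four parameters. Intended to
#' be run once per sequence, against the first frame.
#'
#' @param moving reference DRR (matrix or [radiograph()]).
#' @param fixed fluoroscopy frame of the same shape.
#' @param t_range half-range of the coarse translation search in pixels
#'   (default 1/4 of the image size).
#' @param min_similarity below this final similarity a warning is emitted and
#'   the identity transform returned (default 0.2).
#' @return An [affine_transform2d()] with attribute `similarity`.
#' @export
affine_register <- function(moving, fixed, t_range = NULL,
                            min_similarity = 0.2) {
  m <- norm01(as_pixels(moving)); f <- norm01(as_pixels(fixed))
  if (!all(dim(m) == dim(f))) stop("images must have equal shape")
  t_range <- t_range %||% round(min(dim(m)) / 4)
  # coarse grid over translations only (step 2 px)
  steps <- seq(-t_range, t_range, by = 2)
  best <- c(0, 0); best_s <- -2
  for (ty in steps) for (tx in steps) {
    s <- warp_similarity(c(tx, ty, 0, 1), m, f)
    if (s > best_s) { best_s <- s; best <- c(tx, ty) }
  }
  opt <- optim(c(best, 0, 1), function(p) -warp_similarity(p, m, f),
               method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-12,
                              parscale = c(1, 1, 1, 0.02)))
  par <- opt$par
  s <- -opt$value
  if (s < min_similarity) {
    warning("affine registration did not converge (similarity ", signif(s, 3),
            "); returning identity")
    return(structure(affine_transform2d(), similarity = s))
  }
  structure(affine_transform2d(par[1], par[2], par[3], par[4]),
            similarity = s)
}

#' Histogram matching to a reference image
#'
#' Monotone remap of gray levels so the 8-bit (256-bin) empirical CDF of the
#' output matches the reference CDF. Geometry is unchanged. A constant
#' reference maps everything to that constant.
#'
#' @param image,reference matrices or [radiograph()]s (any positive scale;
#'   internally quantized to 8-bit over each image's own range).
#' @return matrix on the `[0, 1]` scale (multiples of 1/255).
#' @export
histogram_match <- function(image, reference) {
  x <- as_pixels(image); ref <- as_pixels(reference)
  rr <- range(ref)
  if (rr[2] - rr[1] <= 0) {
    lev <- if (max(ref) > 1) rr[1] / 255 else rr[1]
    return(matrix(lev, nrow(x), ncol(x)))
  }
  qx <- round(norm01(x) * 255)
  qr <- round(norm01(ref) * 255)
  cdf_x <- cumsum(tabulate(qx + 1L, 256)) / length(qx)
  cdf_r <- cumsum(tabulate(qr + 1L, 256)) / length(qr)
  # smallest reference level whose CDF reaches the input level's CDF
  lut <- vapply(0:255, function(g) {
    which(cdf_r >= cdf_x[g + 1])[1] - 1L
  }, 0L)
  matrix(lut[qx + 1L] / 255, nrow(x), ncol(x))
}

#' 5x5 median smoothing
#'
#' Each pixel is replaced by the median of its 5x5 neighborhood; borders are
#' reflected. Shape preserved.
#'
#' @param image matrix or [radiograph()].
#' @return matrix of the same shape.
#' @export
median_smooth <- function(image) {
  .median5_cpp(as_pixels(image))
}

#' Adjust a fluoroscopy sequence toward the DRR domain
#'
#' Registers the reference DRR against the first frame once, then per frame:
#' resample into DRR geometry, histogram match to the DRR, 5x5 median smooth.
#'
#' @param frames list of matrices or [radiograph()]s.
#' @param reference_drr the reference DRR.
#' @param register run the registration step (default TRUE; set FALSE when
#'   frames are already geometrically aligned).
#' @return list of adjusted frames (matrices on `[0, 1]`), with the
#'   registration transform in attribute `transform`.
#' @export
adjust_sequence <- function(frames, reference_drr, register = TRUE) {
  stopifnot(length(frames) >= 1)
  drr <- as_pixels(reference_drr)
  tf <- if (register) affine_register(drr, as_pixels(frames[[1]]))
        else affine_transform2d()
  out <- lapply(frames, function(fr) {
    px <- as_pixels(fr)
    if (register) px <- apply_affine(px, tf)
    median_smooth(histogram_match(px, drr))
  })
  attr(out, "transform") <- tf
  out
}
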