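# NCC template-matching tumor tracker.
#
# The similarity is the printed template-matching form: cross-correlation
# normalized by the product of the window and template root energies, WITHOUT
# mean subtraction. (The common zero-mean NCC variant is available behind
# `zero_mean = TRUE` but is not the default.) Matching is integer-pixel.

#' Tracking template
#'
#' @param patch numeric matrix (w x h template patch) with nonzero energy.
#' @param anchor `(x = col, y = row)` of the patch centre in frame-1
#'   coordinates (pixels).
#' @return An object of class `tracking_template`.
#' @export
tracking_template <- function(patch, anchor) {
  patch <- as_pixels(patch)
  if (nrow(patch) < 1 || ncol(patch) < 1) stop("template must be non-empty")
  if (sum(patch^2) == 0) stop("template has zero energy")
  structure(list(patch = patch, anchor = c(x = anchor[[1]], y = anchor[[2]])),
            class = "tracking_template")
}

#' Extract a template from a frame ROI
#'
#' @param frame matrix or [radiograph()] (frame 1 of the sequence).
#' @param x,y centre of the ROI (pixels, `x` = column).
#' @param half_size half-width of the square ROI; the template is
#'   `(2 * half_size + 1)^2`.
#' @return A [tracking_template()].
#' @export
template_from_roi <- function(frame, x, y, half_size) {
  px <- as_pixels(frame)
  rows <- (y - half_size):(y + half_size)
  cols <- (x - half_size):(x + half_size)
  if (min(rows) < 1 || max(rows) > nrow(px) || min(cols) < 1 ||
      max(cols) > ncol(px))
    stop("ROI extends outside the frame")
  tracking_template(px[rows, cols], anchor = c(x = x, y = y))
}

#' Normalized cross-correlation at one search position
#'
#' Evaluates the similarity of the frame window whose top-left pixel is at
#' column `u`, row `v` (1-based) against the template. Values lie in
#' `[-1, 1]`; for strictly positive images in `(0, 1]`.
#'
#' @param frame matrix or [radiograph()].
#' @param template a [tracking_template()] or matrix.
#' @param u,v 1-based column/row of the window's top-left corner.
#' @param zero_mean subtract window and template means first (default FALSE,
#'   matching the printed form).
#' @return scalar similarity.
#' @export
ncc <- function(frame, template, u, v, zero_mean = FALSE) {
  f <- as_pixels(frame)
  t_ <- if (inherits(template, "tracking_template")) template$patch
        else as_pixels(template)
  h <- nrow(t_); w <- ncol(t_)
  if (v < 1 || u < 1 || v + h - 1 > nrow(f) || u + w - 1 > ncol(f))
    stop("search window lies outside the frame")
  win <- f[v:(v + h - 1), u:(u + w - 1)]
  if (zero_mean) {
    win <- win - mean(win)
    t_ <- t_ - mean(t_)
  }
  en <- sqrt(sum(win^2)) * sqrt(sum(t_^2))
  if (en == 0) {
    if (sum(t_^2) == 0) stop("template has zero energy")
    return(0)
  }
  sum(win * t_) / en
}

#' Tumor trajectory
#'
#' @param positions data.frame (or 2-column matrix) of per-frame `(x, y)`
#'   template-centre positions in pixels.
#' @param pixel_to_mm mm per pixel, scalar or `(row, col)` pair.
#' @return An object of class `trajectory` with `$positions` (px) and
#'   `$positions_mm`.
#' @export
trajectory <- function(positions, pixel_to_mm = 1) {
  positions <- as.data.frame(positions)
  names(positions)[1:2] <- c("x", "y")
  stopifnot(all(is.finite(positions$x)), all(is.finite(positions$y)))
  if (length(pixel_to_mm) == 1) pixel_to_mm <- rep(pixel_to_mm, 2)
  mm <- data.frame(x = positions$x * pixel_to_mm[2],
                   y = positions$y * pixel_to_mm[1])
  structure(list(positions = positions, positions_mm = mm,
                 pixel_to_mm = pixel_to_mm), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$positions), " frames, ",
      paste(signif(x$pixel_to_mm, 3), collapse = "x"), " mm/px\n", sep = "")
  invisible(x)
}

traj_mm <- function(x) {
  if (inherits(x, "trajectory")) return(as.matrix(x$positions_mm))
  x <- as.matrix(as.data.frame(x))
  x[, 1:2, drop = FALSE]
}

#' Track a template through a fluoroscopy sequence
#'
#' Per frame, the template is matched by exhaustive argmax of [ncc()] over a
#' square search window centred on the previous frame's position
#' (integer-pixel). Ties among strictly better candidates are broken by the
#' first maximum in row-major scan order (smallest row, then column); an
#' exact tie with the previous position keeps the previous position, so
#' featureless frames do not drift. Windows that would leave the frame are
#' clipped with a warning.
#'
#' @param frames list of matrices or [radiograph()]s.
#' @param template a [tracking_template()] (from frame 1).
#' @param search_radius half-width of the search window in pixels
#'   (default 20).
#' @param pixel_to_mm mm per pixel for the returned trajectory.
#' @param zero_mean use the zero-mean NCC variant (default FALSE).
#' @return A [trajectory()] of template-centre positions.
#' @export
track_sequence <- function(frames, template, search_radius = 20,
                           pixel_to_mm = 1, zero_mean = FALSE) {
  stopifnot(inherits(template, "tracking_template"), length(frames) >= 1)
  th <- nrow(template$patch); tw <- ncol(template$patch)
  # current top-left (row, col), 1-based
  r_cur <- round(template$anchor[["y"]] - (th - 1) / 2)
  c_cur <- round(template$anchor[["x"]] - (tw - 1) / 2)
  pos <- matrix(NA_real_, length(frames), 2)
  clipped <- FALSE
  for (t_ in seq_along(frames)) {
    f <- as_pixels(frames[[t_]])
    r_lo <- r_cur - search_radius; r_hi <- r_cur + search_radius
    c_lo <- c_cur - search_radius; c_hi <- c_cur + search_radius
    if (r_lo < 1 || c_lo < 1 || r_hi + th - 1 > nrow(f) ||
        c_hi + tw - 1 > ncol(f)) {
      clipped <- TRUE
      r_lo <- max(1, r_lo); c_lo <- max(1, c_lo)
      r_hi <- min(nrow(f) - th + 1, r_hi)
      c_hi <- min(ncol(f) - tw + 1, c_hi)
    }
    r_init <- min(max(r_cur, r_lo), r_hi)
    c_init <- min(max(c_cur, c_lo), c_hi)
    hit <- .ncc_search_cpp(f, template$patch, r_lo - 1L, r_hi - 1L,
                           c_lo - 1L, c_hi - 1L, r_init - 1L, c_init - 1L,
                           zero_mean)
    r_cur <- hit$row + 1L
    c_cur <- hit$col + 1L
    pos[t_, ] <- c(c_cur + (tw - 1) / 2, r_cur + (th - 1) / 2) # centre (x, y)
  }
  if (clipped) warning("search window clipped at the frame border")
  trajectory(data.frame(x = pos[, 1], y = pos[, 2]), pixel_to_mm = pixel_to_mm)
}
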