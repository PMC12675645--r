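# Quantitative evaluation: tracking error (RMSE), tracking success rate
# (TSR), image quality (PSNR, SSIM), and paired bootstrap comparison.

#' Root mean square tracking error
#'
#' `sqrt((1/n) * sum((x_g - x)^2 + (y_g - y)^2))` over frames, in mm.
#'
#' @param traj,gt [trajectory()]s (or 2-column matrices in mm) of equal
#'   length: tracked and ground-truth positions.
#' @return scalar RMSE in mm.
#' @export
rmse <- function(traj, gt) {
  a <- traj_mm(traj); b <- traj_mm(gt)
  if (nrow(a) != nrow(b)) stop("trajectories have different lengths")
  sqrt(mean((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2))
}

#' Per-frame Euclidean tracking errors (mm)
#' @inheritParams rmse
#' @return numeric vector of per-frame errors.
#' @export
tracking_errors <- function(traj, gt) {
  a <- traj_mm(traj); b <- traj_mm(gt)
  if (nrow(a) != nrow(b)) stop("trajectories have different lengths")
  sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
}

#' Tracking success rate
#'
#' Percentage of frames whose Euclidean tracking error is strictly below 25%
#' of the maximum tumor movement range.
#'
#' @param traj,gt as in [rmse()], or `traj` a numeric vector of per-frame
#'   errors in mm (then `gt` is omitted).
#' @param motion_range maximum tumor movement range in mm (> 0).
#' @return percentage in `[0, 100]`.
#' @export
tsr <- function(traj, gt = NULL, motion_range) {
  if (motion_range <= 0) stop("motion_range must be positive")
  err <- if (is.numeric(traj) && is.null(dim(traj)) && is.null(gt)) traj
         else tracking_errors(traj, gt)
  100 * mean(err < 0.25 * motion_range)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)`; identical images give `Inf`.
#'
#' @param a,b numeric matrices of identical shape.
#' @param max_value peak intensity (255 for 8-bit images).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_value = 255) {
  a <- as_pixels(a); b <- as_pixels(b)
  if (!all(dim(a) == dim(b))) stop("images must have equal shape")
  if (max_value <= 0) stop("max_value must be positive")
  m <- mean((a - b)^2)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Structural similarity index (single scale)
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5), stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, averaged over the valid region of
#' the map.
#'
#' @param a,b numeric matrices of identical shape (at least 11x11).
#' @param max_value dynamic range L (255 for 8-bit images).
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, max_value = 255) {
  a <- as_pixels(a); b <- as_pixels(b)
  if (!all(dim(a) == dim(b))) stop("images must have equal shape")
  if (any(dim(a) < 11)) stop("images must be at least 11x11")
  g <- exp(-((-5:5)^2) / (2 * 1.5^2))
  g <- g / sum(g)
  mu_a <- .sepconv2_valid_cpp(a, g)
  mu_b <- .sepconv2_valid_cpp(b, g)
  saa <- .sepconv2_valid_cpp(a * a, g) - mu_a^2
  sbb <- .sepconv2_valid_cpp(b * b, g) - mu_b^2
  sab <- .sepconv2_valid_cpp(a * b, g) - mu_a * mu_b
  c1 <- (0.01 * max_value)^2
  c2 <- (0.03 * max_value)^2
  m <- ((2 * mu_a * mu_b + c1) * (2 * sab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (saa + sbb + c2))
  mean(m)
}

#' Paired bootstrap comparison of two tracking-error arms
#'
#' Frame indices are resampled with replacement `B` times (the same indices
#' for both arms, preserving the pairing); the chosen statistic (RMSE by
#' default, or TSR) is recomputed per arm and resample. The two-sided p-value
#' is `2 * min(P(diff <= 0), P(diff >= 0))` with +1 smoothing; per-arm 95%
#' percentile confidence intervals are returned.
#'
#' @param errors_a,errors_b numeric vectors of per-frame errors in mm (equal
#'   lengths).
#' @param B number of bootstrap resamples (>= 100, default 1000).
#' @param alpha significance level (default 0.05).
#' @param statistic `"rmse"` or `"tsr"`.
#' @param motion_range required when `statistic = "tsr"`.
#' @param seed optional integer seed for reproducible resampling.
#' @return list with `p_value`, `reject`, `stat_a`, `stat_b`, `ci_a`, `ci_b`,
#'   `B`, `statistic`.
#' @export
paired_bootstrap_test <- function(errors_a, errors_b, B = 1000, alpha = 0.05,
                                  statistic = c("rmse", "tsr"),
                                  motion_range = NULL, seed = NULL) {
  statistic <- match.arg(statistic)
  n <- length(errors_a)
  if (length(errors_b) != n) stop("error vectors have different lengths")
  if (B < 100) stop("B must be >= 100")
  stat_fn <- if (statistic == "rmse") {
    function(e) sqrt(mean(e^2))
  } else {
    if (is.null(motion_range)) stop("motion_range required for TSR statistic")
    function(e) 100 * mean(e < 0.25 * motion_range)
  }
  run <- function() {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    sa <- apply(idx, 2, function(i) stat_fn(errors_a[i]))
    sb <- apply(idx, 2, function(i) stat_fn(errors_b[i]))
    list(sa = sa, sb = sb)
  }
  bs <- if (is.null(seed)) run() else with_seed(seed, run())
  d <- bs$sa - bs$sb
  p <- 2 * min((1 + sum(d <= 0)) / (B + 1), (1 + sum(d >= 0)) / (B + 1))
  p <- min(p, 1)
  list(p_value = p, reject = p < alpha,
       stat_a = stat_fn(errors_a), stat_b = stat_fn(errors_b),
       ci_a = unname(quantile(bs$sa, c(alpha / 2, 1 - alpha / 2))),
       ci_b = unname(quantile(bs$sb, c(alpha / 2, 1 - alpha / 2))),
       B = B, statistic = statistic)
}

#' Per-sequence tracking report
#'
#' Bundles the per-frame errors and the summary statistics for one tracked
#' sequence, with the success threshold fixed at 25% of the motion range.
#'
#' @param errors numeric vector of per-frame Euclidean errors (mm).
#' @param motion_range maximum tumor movement range (mm).
#' @param comparison optional result of [paired_bootstrap_test()] against a
#'   second arm.
#' @return An object of class `tracking_report`.
#' @export
tracking_report <- function(errors, motion_range, comparison = NULL) {
  structure(list(errors = errors,
                 rmse = sqrt(mean(errors^2)),
                 tsr = 100 * mean(errors < 0.25 * motion_range),
                 motion_range = motion_range,
                 success_threshold = 0.25 * motion_range,
                 comparison = comparison),
            class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat(sprintf("<tracking_report> %d frames: RMSE %.3f mm, TSR %.1f%% (threshold %.2f mm)\n",
              length(x$errors), x$rmse, x$tsr, x$success_threshold))
  invisible(x)
}
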