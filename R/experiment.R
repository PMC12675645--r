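# Desk-scale experiment harness: held-out synthesis evaluation (PSNR/SSIM on
# unseen couch-angle cases) and the SE-vs-DES tracking comparison on
# simulated rib-overlap sequences.
#
# Ground truth is the projected phantom tumor centroid (exact), replacing the
# manual contours of clinical practice. Because the integer template anchor
# differs from the continuous centroid by a constant sub-pixel offset, the
# tracked trajectory is aligned to the ground truth at frame 1 (the frame the
# ROI is defined on), so a perfect tracker scores exactly zero error.

#' Configure one simulated fluoroscopy case
#'
#' @param theta,phi couch angles in degrees.
#' @param gantry gantry angle in degrees (fixed over the sequence), or, with
#'   `gantry_sweep = TRUE`, ignored.
#' @param gantry_sweep sweep the gantry linearly from 3.6 to 360 degrees
#'   across the sequence (default FALSE; one rotation per frame makes
#'   swept cases considerably slower to simulate).
#' @param n_frames sequence length (default 150).
#' @param cycles respiratory cycles spanned (default 5);
#'   `n_frames / cycles` frames per cycle.
#' @param tumor_diameter mm (default 10).
#' @param amplitude superior-inferior motion amplitude in mm (default 10).
#' @param tumor_center optional tumor centre override (centred mm).
#' @return An object of class `case_config`.
#' @export
case_config <- function(theta = 0, phi = 0, gantry = 180,
                        gantry_sweep = FALSE, n_frames = 150L,
                        cycles = 5L, tumor_diameter = 10, amplitude = 10,
                        tumor_center = NULL) {
  stopifnot(n_frames %% cycles == 0, tumor_diameter > 0)
  structure(list(theta = theta, phi = phi, gantry = gantry,
                 gantry_sweep = isTRUE(gantry_sweep),
                 n_frames = as.integer(n_frames), cycles = as.integer(cycles),
                 tumor_diameter = tumor_diameter, amplitude = amplitude,
                 tumor_center = tumor_center),
            class = "case_config")
}

#' Default held-out test cases (couch-angle pairs unseen in training)
#'
#' The four couch pairs (9,28), (17,5), (20,32), (25,21) degrees; training
#' grids only ever contain pairs with `theta == phi`, so these are
#' structurally unseen.
#'
#' @param ... passed to [case_config()] for every case.
#' @return list of four [case_config()]s.
#' @export
default_test_cases <- function(...) {
  pairs <- list(c(9, 28), c(17, 5), c(20, 32), c(25, 21))
  lapply(pairs, function(p) case_config(theta = p[1], phi = p[2], ...))
}

#' Desk-scale phantom/detector settings for the harness
#'
#' 64^3 voxels at 4 mm (256 mm field of view) projecting to a 64x64 detector;
#' chosen so a full train-and-evaluate cycle runs on one CPU in minutes.
#'
#' @param shape,spacing detector-resolution grid dimensions and voxel size
#'   (mm).
#' @param supersample rasterize the phantom on a grid this many times finer
#'   and average (bin) the projected rays per detector pixel (default 2).
#'   Removes the voxelization aliasing a coarse grid would imprint on the
#'   images.
#' @return list with `shape`, `spacing` and `supersample`.
#' @export
desk_sim_settings <- function(shape = c(64L, 64L, 64L), spacing = 4,
                              supersample = 2L) {
  list(shape = as.integer(shape), spacing = spacing,
       supersample = as.integer(supersample))
}

# phantom config matching a case (tumor geometry from the case config)
case_phantom_config <- function(case, sim, ...) {
  phantom_config(shape = sim$shape, spacing = sim$spacing,
                 tumor_center = case$tumor_center,
                 tumor_diameter = case$tumor_diameter,
                 amplitude = case$amplitude, ...)
}

# phase index of frame t (1-based), cycling through all phases per cycle
frame_phase <- function(t_, n_frames, cycles, phase_count) {
  fpc <- n_frames / cycles
  u <- ((t_ - 1) %% fpc) / fpc
  as.integer(floor(u * phase_count) + 1L)
}

#' Simulate one fluoroscopy case (SE, analytic DES, ground truth)
#'
#' Builds each respiratory phase once, rotates and projects at the case
#' angles, computes the analytic DES reference, and records the projected
#' tumor centroid as ground truth.
#'
#' @param case a [case_config()].
#' @param sim simulation settings from [desk_sim_settings()].
#' @param omega subtraction weight (default 0.5).
#' @param ... extra [phantom_config()] overrides.
#' @return list with `se`, `des` (per-frame [radiograph()]s), `gt`
#'   ([trajectory()] in px), `gt_mm` (matrix), `motion_range` (mm),
#'   `pixel_spacing`, `phases`.
#' @export
simulate_case <- function(case, sim = desk_sim_settings(), omega = 0.5, ...) {
  stopifnot(inherits(case, "case_config"))
  ss <- sim$supersample %||% 1L
  fine <- list(shape = sim$shape * ss, spacing = sim$spacing / ss)
  cfg <- case_phantom_config(case, fine, ...)
  specs <- cfg$energy_specs
  phases <- vapply(seq_len(case$n_frames), frame_phase, 0L,
                   n_frames = case$n_frames, cycles = case$cycles,
                   phase_count = cfg$phase_count)
  gammas <- if (isTRUE(case$gantry_sweep))
    seq(3.6, 360, length.out = case$n_frames) else rep(case$gantry, case$n_frames)
  keys <- paste(phases, signif(gammas, 10), sep = "@")
  bin_rg <- function(rg) {
    rg$pixels <- bin_pixels(rg$pixels, ss)
    rg$pixel_spacing <- rg$pixel_spacing * ss
    rg
  }
  mu_cache <- list()
  per_key <- list()
  for (i in which(!duplicated(keys))) {
    p <- phases[i]
    pk <- as.character(p)
    if (is.null(mu_cache[[pk]])) {
      vol <- build_phantom(cfg, p)
      mu_cache[[pk]] <- list(HE = attenuation_volume(vol, specs$HE),
                             LE = attenuation_volume(vol, specs$LE),
                             centroid = tumor_centroid(vol))
    }
    ang <- acquisition_angles(case$theta, case$phi, gammas[i])
    R <- rotation_matrix(ang)
    he <- bin_rg(project(rotate_volume(mu_cache[[pk]]$HE, R),
                         meta = list(energy = "HE", phase = p, angles = ang,
                                     kind = "SE")))
    le <- bin_rg(project(rotate_volume(mu_cache[[pk]]$LE, R),
                         meta = list(energy = "LE", phase = p, angles = ang,
                                     kind = "LE")))
    gt_f <- project_point(mu_cache[[pk]]$centroid, R, cfg$shape, cfg$spacing)
    gt <- (gt_f + 0.5 * (ss - 1)) / ss # fine-grid px -> binned detector px
    per_key[[keys[i]]] <- list(se = he,
                               des = des_subtract(he, le, omega = omega),
                               gt = gt)
  }
  gt_px <- t(vapply(keys, function(k) per_key[[k]]$gt, c(x = 0, y = 0)))
  px_sp <- per_key[[1]]$se$pixel_spacing
  gt_traj <- trajectory(data.frame(x = gt_px[, 1], y = gt_px[, 2]),
                        pixel_to_mm = px_sp)
  gt_mm <- as.matrix(gt_traj$positions_mm)
  motion_range <- max(stats::dist(gt_mm))
  list(se = lapply(keys, function(k) per_key[[k]]$se),
       des = lapply(keys, function(k) per_key[[k]]$des),
       gt = gt_traj, gt_mm = gt_mm, motion_range = motion_range,
       pixel_spacing = px_sp, phases = phases, gammas = gammas,
       phantom_config = cfg,
       angles = acquisition_angles(case$theta, case$phi, gammas[1]))
}

# 8-bit export after per-image max-normalization (the display convention:
# divide by the image maximum, preserving the black level)
quantize8 <- function(x) {
  m <- max(x)
  if (m <= 0) return(matrix(0, nrow(x), ncol(x)))
  round(pmin(pmax(x / m, 0), 1) * 255)
}

# 2x2 (or ss x ss) detector binning: average of the fine-grid rays hitting
# one physical detector pixel
bin_pixels <- function(px, ss) {
  if (ss == 1) return(px)
  h <- nrow(px) / ss; w <- ncol(px) / ss
  out <- matrix(0, h, w)
  for (dr in seq_len(ss)) for (dc in seq_len(ss))
    out <- out + px[seq(dr, nrow(px), ss), seq(dc, ncol(px), ss)]
  out / ss^2
}

#' Held-out synthesis evaluation (PSNR / SSIM per case)
#'
#' For each case: simulate the SE frames, synthesize DES with the model, and
#' compare against the analytic DES reference at 8-bit after per-image
#' min-max normalization. `model = "analytic"` substitutes the analytic DES
#' operator itself, which gives the identity upper bound (SSIM 1, PSNR Inf).
#'
#' @param model a trained `des_synthesizer`, or `"analytic"`.
#' @param cases list of [case_config()]s (default [default_test_cases()]).
#' @param sim simulation settings.
#' @param omega subtraction weight.
#' @return data.frame with one row per case: `theta`, `phi`, `psnr` (dB,
#'   8-bit scale), `ssim`, `n_frames`.
#' @export
run_synthesis_eval <- function(model, cases = default_test_cases(),
                               sim = desk_sim_settings(), omega = 0.5) {
  rows <- lapply(cases, function(case) {
    s <- simulate_case(case, sim, omega = omega)
    # metrics per distinct (phase, gantry) frame, weighted by occurrences
    keys <- paste(s$phases, s$gammas)
    uq <- which(!duplicated(keys))
    wts <- as.numeric(table(factor(keys, levels = keys[uq])))
    vals <- vapply(uq, function(i) {
      ref <- quantize8(s$des[[i]]$pixels)
      syn <- if (identical(model, "analytic")) ref
             else quantize8(synthesize(model, s$se[[i]])$pixels)
      c(psnr = psnr(syn, ref, 255), ssim = ssim(syn, ref, 255))
    }, c(psnr = 0, ssim = 0))
    data.frame(theta = case$theta, phi = case$phi,
               psnr = sum(vals["psnr", ] * wts) / sum(wts),
               ssim = sum(vals["ssim", ] * wts) / sum(wts),
               n_frames = case$n_frames)
  })
  do.call(rbind, rows)
}

#' SE-vs-DES tumor tracking comparison on simulated sequences
#'
#' For each case, tracks the tumor on the SE arm and on the DES arm (analytic
#' by default, or model-synthesized), scores both against the projected
#' centroid ground truth, and runs the paired bootstrap comparison on the
#' per-frame errors.
#'
#' @param cases list of [case_config()]s.
#' @param sim simulation settings.
#' @param des_source `"analytic"` or a trained `des_synthesizer`.
#' @param search_radius NCC search half-width in px (default 20).
#' @param template_half template ROI half-width in px (default: tumor radius
#'   in px + 2).
#' @param B bootstrap resamples (default 1000).
#' @param seed master seed for the bootstrap.
#' @param omega subtraction weight.
#' @param ... extra [phantom_config()] overrides (e.g. `energy_specs`),
#'   forwarded to [simulate_case()].
#' @return list with `cases` (per-case data.frame mirroring the tracking
#'   comparison table: RMSE/TSR per arm, 95% CIs, bootstrap p-values and
#'   significance flags) and `average` (cross-case means).
#' @export
run_tracking_comparison <- function(cases, sim = desk_sim_settings(),
                                    des_source = "analytic",
                                    search_radius = 20, template_half = NULL,
                                    B = 1000, seed = 1L, omega = 0.5, ...) {
  rows <- vector("list", length(cases))
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    s <- simulate_case(case, sim, omega = omega, ...)
    # degenerate guard: a motionless tumor has zero range; floor the success
    # threshold at one pixel so TSR stays defined
    motion_range <- max(s$motion_range, min(s$pixel_spacing))
    th <- template_half %||%
      (ceiling(case$tumor_diameter / 2 / min(s$pixel_spacing)) + 2)
    arm_frames <- list(
      SE = lapply(s$se, function(r) r$pixels),
      DES = if (identical(des_source, "analytic"))
        lapply(s$des, function(r) r$pixels)
      else lapply(s$se, function(r) pmax(synthesize(des_source, r)$pixels, 1e-6))
    )
    gt_px <- as.matrix(s$gt$positions)
    x0 <- round(gt_px[1, 1]); y0 <- round(gt_px[1, 2])
    errs <- lapply(arm_frames, function(frames) {
      tmpl <- template_from_roi(frames[[1]], x0, y0, th)
      tr <- track_sequence(frames, tmpl, search_radius = search_radius,
                           pixel_to_mm = s$pixel_spacing)
      # align at frame 1: the ROI definition frame is error-free by definition
      pos <- as.matrix(tr$positions)
      pos <- sweep(pos, 2, pos[1, ] - gt_px[1, ])
      aligned <- trajectory(pos, pixel_to_mm = s$pixel_spacing)
      tracking_errors(aligned, s$gt)
    })
    bt_rmse <- paired_bootstrap_test(errs$SE, errs$DES, B = B,
                                     seed = derive_seed(seed, paste0("rmse-", ci)))
    bt_tsr <- paired_bootstrap_test(errs$SE, errs$DES, B = B, statistic = "tsr",
                                    motion_range = motion_range,
                                    seed = derive_seed(seed, paste0("tsr-", ci)))
    rows[[ci]] <- data.frame(
      case = ci, theta = case$theta, phi = case$phi, gantry = case$gantry,
      motion_range = motion_range,
      rmse_se = bt_rmse$stat_a, rmse_des = bt_rmse$stat_b,
      rmse_se_ci_lo = bt_rmse$ci_a[1], rmse_se_ci_hi = bt_rmse$ci_a[2],
      rmse_des_ci_lo = bt_rmse$ci_b[1], rmse_des_ci_hi = bt_rmse$ci_b[2],
      p_rmse = bt_rmse$p_value, sig_rmse = bt_rmse$reject,
      tsr_se = bt_tsr$stat_a, tsr_des = bt_tsr$stat_b,
      tsr_se_ci_lo = bt_tsr$ci_a[1], tsr_se_ci_hi = bt_tsr$ci_a[2],
      tsr_des_ci_lo = bt_tsr$ci_b[1], tsr_des_ci_hi = bt_tsr$ci_b[2],
      p_tsr = bt_tsr$p_value, sig_tsr = bt_tsr$reject)
  }
  tab <- do.call(rbind, rows)
  avg <- colMeans(tab[, c("rmse_se", "rmse_des", "tsr_se", "tsr_des")])
  list(cases = tab, average = avg)
}

#' Simulation settings for the tracking experiments
#'
#' 128^3 voxels at 2 mm: the same 256 mm thorax as [desk_sim_settings()] but
#' at a resolution where clinical tumor displacements span many pixels, the
#' regime in which template tracking is meaningful.
#'
#' @return list with `shape` and `spacing`.
#' @export
tracking_sim_settings <- function() {
  list(shape = c(128L, 128L, 128L), spacing = 2)
}

#' Seeded rib-overlap tracking cases
#'
#' Generates case configurations whose tumor size, motion amplitude and
#' position are jittered per seed so the tumor path crosses rib shadows at
#' varying depths — the scenario where bone suppression should help
#' tracking. Tumor diameters (18-28 mm) and amplitudes (8-18 mm) follow the
#' range of clinical lung-SBRT cohorts; pair with
#' [tracking_sim_settings()] and [cortical_energy_specs()].
#'
#' @param n_cases number of cases (default 10).
#' @param seed master seed.
#' @param sim simulation settings (used to scale the jitter to the grid).
#' @return list of [case_config()]s.
#' @export
rib_overlap_cases <- function(n_cases = 10, seed = 1L,
                              sim = tracking_sim_settings()) {
  half <- sim$shape * sim$spacing / 2
  base <- phantom_config(shape = sim$shape, spacing = sim$spacing)
  with_seed(derive_seed(seed, "rib-overlap-cases"), {
    lapply(seq_len(n_cases), function(i) {
      ctr <- base$tumor_center +
        c(runif(1, -0.05, 0.05) * half[1], 0, runif(1, -0.10, 0.10) * half[3])
      case_config(theta = 0, phi = 0, gantry = 180,
                  n_frames = 60L, cycles = 2L,
                  tumor_diameter = runif(1, 18, 28),
                  amplitude = runif(1, 8, 18), tumor_center = ctr)
    })
  })
}
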