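---
title: "Dual-energy subtraction synthesis and markerless tumor tracking: methods"
author: "fluorodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-energy subtraction synthesis and markerless tumor tracking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lung tumors move with respiration, and during radiotherapy they must be
localized in real time on kV fluoroscopy. Template-matching trackers degrade
when ribs overlap the tumor: the bone shadow dominates the local intensity
pattern and the tracker locks onto the (static) rib rather than the (moving)
tumor. Dual-energy (DE) imaging suppresses bone by weighted logarithmic
subtraction of a high-energy (HE, ~120 kVp) and a low-energy (LE, ~60 kVp)
exposure, but requires dedicated hardware. `fluorodes` implements the
simulation-to-synthesis alternative: train a residual U-Net to map a
single-energy (SE) image to its dual-energy subtraction (DES) counterpart,
using training pairs generated entirely from a digital thorax phantom, and
quantify the tracking benefit with a normalized cross-correlation (NCC)
tracker and RMSE/TSR statistics.

## The phantom and its stated world

Licensed anthropomorphic phantoms are unavailable here, so the package
generates its own: an elliptical soft-tissue torso, two ellipsoidal lungs, a
posterior spinal column, ten curved rib arcs per side that drift inferiorly
from back to front, and a spherical tumor (default diameter 10 mm) inside
the right lung. All solids are analytic and rasterized deterministically,
so phantom volumes are bit-reproducible.

Respiratory motion uses the standard surrogate `A * sin^2(pi (p - 1) / P)`
over `P = 10` phases, with phase 1 the full-exhale reference and amplitude
`A = 10` mm by default (a typical superior–inferior excursion for a
lower-lobe tumor). Only the tumor translates: moving lung boundaries as well
would violate the per-material volume-conservation property we test for at
coarse grids, and nothing downstream depends on diaphragm motion — the
tracking problem only needs a moving tumor behind static ribs.

Attenuation is monoenergetic per material (effective surrogates for the two
tube voltages), in 1/cm: soft tissue 0.18/0.25 (HE/LE), lung 0.04/0.06,
bone 0.30/0.60, tumor 0.19/0.27. Bone is constructed with an HE/LE ratio of
exactly 0.5 so that the canonical soft-tissue weight `omega = 0.5` is also
the *exact* bone-cancelling weight — this turns bone suppression into an
analytic oracle (below) instead of an approximate one.

## Projection

Volumes are rotated by `R = Rx(theta) Ry(phi) Rz(gamma)` (couch angles
`theta`, `phi`; gantry `gamma`) about the grid centre with trilinear
resampling. The elemental matrices follow the published convention of this
workflow literally; note two quirks we preserve and document rather than
"fix": the printed `Ry` is the transpose of the common right-handed form,
and the stray symbol at `Rz(3,2)` is read as a typographical zero. Both
choices still yield proper rotations and all self-consistency properties
(orthonormality, round trips) hold.

Projection is parallel-beam along the anterior–posterior axis with
`I = I0 exp(-integral mu dl)` and no noise, scatter, or detector model. The
ray integral of an axis-aligned parallel beam is exactly the voxel sum times
the step, which gives closed-form oracles (a 0.1/cm x 10 cm slab projects to
`exp(-1)` exactly). A uniform half-voxel-stepped oblique integrator was
considered and rejected: rotating the volume first and integrating
axis-aligned is algebraically identical for the parallel geometry and keeps
the oracle exact.

Rasterizing analytic solids on a coarse grid imprints aliasing (jagged
voxel edges) on every projection. The harness therefore supersamples: the
phantom is built on a grid twice as fine as the detector and the projected
rays are averaged 2x2 per detector pixel — exactly what a finite detector
element does physically. This matters for learning: the aliasing is the
highest-frequency content in the image, and at desk scale it consumed a
disproportionate share of the small network's capacity.

## Dual-energy subtraction and the central oracle

The subtraction is `ln I_DES = ln I_HE - omega ln I_LE` (intensities floored
at 1e-8 before logs; the floor is inactive for projections, which are
strictly positive). Because trilinear interpolation and the ray integral are
both linear in the attenuation grid, and bone's HE coefficient is exactly
`omega` times its LE coefficient, the bone contribution cancels *exactly*:
the DES image of a ribbed phantom equals the DES image of the same phantom
with its bones replaced by air, pixel for pixel, to machine precision — even
after arbitrary rotations. This is the package's central correctness oracle
and an acceptance criterion (tolerance 1e-6 in the log domain).

DES images are kept internally in both intensity and log domain
(`log_pixels` attribute); exports are per-image max-normalized, a display
choice the source protocol leaves open.

## Training data

The full published grid is 10 phases x 36 couch pairs
`(0,0), (1,1), ..., (35,35)` x 100 gantry angles (3.6 degree steps) =
36,000 pairs; `enumerate_training_grid()` reproduces it exactly. The
desk-scale protocol subsamples it to 500 pairs, spending the budget where
generalization needs it: 10 couch values spanning 0–35 degrees (the
held-out cases differ from training mainly in their couch geometry, so the
couch diagonal is sampled densely) x 5 gantry angles x 10 phases.

Each pair can receive one sampled geometric augmentation, applied
identically to both members: scaling in [0.8, 1.2] (centre-cropped or
zero-padded back), or a crop to 50–100% of size at a uniform-random
position, zero-padded back in place. Crop placement is uniform because the
source protocol does not state it; per-pair seeds derive from the master
seed so the whole dataset is reproducible. The desk-scale acceptance
protocol trains without augmentation: its purpose — simulating the varied
fields of view of clinical acquisitions — addresses a domain the synthetic
held-out evaluation never enters, while the zero-padded borders it
introduces measurably slow the already-short 20-epoch schedule. Pipelines
headed for foreign-domain frames should keep `augment = TRUE`.

## The residual U-Net

No deep-learning framework exists for R in this environment, so the network
is implemented directly (im2col convolutions in C++, the graph, backprop and
Adam in R). Architecture choices the source leaves open, fixed here as the
minimal faithful reading of "residual U-Net": 3x3 kernels, ReLU, 2x2
max-pool and nearest-neighbour upsampling, one residual block per level
(two convolutions with an additive shortcut; a 1x1 projection where channel
counts differ), skip connections concatenated `[skip, upsampled]`, a final
linear 1x1 convolution, and no batch normalization. Desk scale is depth 3
with 8 base filters (31,225 parameters) on 64x64 inputs.

The decisive representational choice is the **training domain**. In the
intensity domain the SE-to-DES map is a strong spatially-varying power law
(`I_DES = I_SE * exp(0.5 L_LE)`), and the small network plateaus around
18–25 dB under every variant we benchmarked (global input–output residual,
min-max normalization, batch and clipping changes). In the log
(radiological pathlength) domain the same map is nearly linear pixelwise —
`-ln I_DES ~ 0.3 * (-ln I_SE)` for soft tissue, with localized corrections
where lung and bone mix — and the identical network trains an order of
magnitude further. The source protocol leaves the training domain of the
DES images explicitly open, and the package defaults to
`domain = "log"` with pathlengths capped at `log_cap = 12` (zero pixels
from augmentation padding land on the cap). Per-image min-max normalization
is available (`normalize = TRUE`) but off by default: simulated projections
already live on a canonical physical scale, and a per-image stretch
discards exactly the scale information the mapping depends on. A global
input–output residual and coordinate input channels were implemented and
benchmarked as well; neither helps in the log domain (the target is far
from the identity there) and both default to off.

Training follows the stated protocol: MSE loss, Adam, initial learning rate
0.02 decayed linearly to 1e-4 over the scheduled epochs, 90/10
train/validation split by manifest order, up to 20 epochs at desk scale
(the full protocol's 200 epochs remain configurable). Several details the
source does not state were chosen for the compressed schedule, each
benchmarked on held-out cases:

* batch size 2 — more optimizer steps per epoch at identical cost;
* global-norm gradient clipping at 1.0 — small-batch Adam diverges at the
  high initial learning rate without it;
* collapse restarts — a small fraction of initializations still die to
  constant (per-image-mean) predictions within the first epochs; the loss
  then sits exactly at the target-variance floor, which is detected and the
  initialization deterministically re-seeded (at most three times);
* decoupled weight decay 0.05 — 500 images overfit within 20 epochs, and
  the decay recovers 2–3 dB of held-out PSNR on the worst initializations;
* Polyak tail averaging of the weights over the last quarter of the
  schedule — damps the end-of-run optimizer wobble;
* two residual blocks per level and a zero-initialized output head.

Gradients are verified against central finite differences in the test
suite (relative error < 1e-5). At this scale the held-out synthesis
quality reaches roughly PSNR 33 dB and SSIM 0.92–0.93 minimum over the
four test cases; the full-scale protocol's published figures (over 40 dB,
0.993) require the 36,000-pair, 200-epoch configuration that a desk CPU
cannot run, with the residual gap dominated by generalization to
off-diagonal couch pairs that the training protocol never contains.

## Clinical-style adjustment

Frames from a different imaging chain are brought into the DRR-like domain
before synthesis, in the fixed order: one affine registration of the
reference DRR against the first frame (translation, rotation, isotropic
scale, maximizing a normalized-correlation similarity with a coarse
translation search plus Nelder–Mead refinement — the source names only
"affine" and a toolkit), then per frame histogram matching to the DRR
(monotone 256-bin quantile mapping) and a 5x5 median filter with reflected
borders (border policy unstated in the source; reflection avoids halo
artifacts at frame edges).

## Tracking and evaluation

The NCC is implemented exactly as printed in the source protocol — cross
correlation normalized by root energies *without* mean subtraction (the
usual zero-mean variant sits behind a flag, not the default). Matching is
integer-pixel by exhaustive argmax over a +/-20 px window centred on the
previous position. Ties among strictly better candidates resolve to the
first maximum in row-major order; an exact tie with the previous position
keeps it, so featureless frames do not drift.

RMSE is the per-frame Euclidean error root mean square; TSR counts frames
with error strictly below 25% of the maximum tumor movement range ("below"
read as strict). PSNR uses the 8-bit peak (255); SSIM is single-scale with
the original 11x11 Gaussian window (sigma 1.5) and stabilizers
`(0.01 L)^2`, `(0.03 L)^2`, averaged over the valid (un-padded) region.
The paired bootstrap resamples frame indices i.i.d. (B = 1000 default),
recomputes the statistic per arm on shared indices, and reports the
two-sided p-value with +1 smoothing plus 95% percentile intervals — the
source states only "bootstrap hypothesis testing (p = 0.05)", so the
resampling design is ours and is documented here.

## The experiment harness

Held-out evaluation uses four cases at couch pairs (9, 28), (17, 5),
(20, 32), (25, 21) degrees — angle pairs with `theta != phi` never occur in
training grids, so they are structurally unseen. Each case is 150 frames
over five respiratory cycles; the gantry is held at 180 degrees by default
(a typical anterior–posterior beam; the source is ambiguous about which
angles vary in this experiment — its couch/gantry naming is internally
swapped — and we follow its own angle definitions). A
`gantry_sweep = TRUE` case variant rotates the gantry linearly from 3.6 to
360 degrees across the sequence for users who prefer the other reading;
it is not the default because every frame then needs its own volume
rotation. Quality metrics follow the 8-bit display protocol: each image is
max-normalized (divided by its own maximum — the export convention of this
workflow, which preserves the black level rather than stretching it),
quantized to 8 bits, and compared by PSNR (peak 255) and SSIM.

Ground truth for tracking is the projected phantom tumor centroid — exact,
unlike manual contours — and the tracked trajectory is aligned to it at
frame 1, since the integer ROI anchor differs from the continuous centroid
by a constant sub-pixel offset that no tracker could remove. A motionless
tumor therefore scores exactly zero RMSE, and its degenerate zero motion
range is floored at one pixel so TSR stays defined.

The rib-overlap comparison deserves its own stated world. Template tracking
is only meaningful when tumor displacements span many pixels — clinically,
sub-millimetre detector pixels see 10–80 px of motion — so the tracking
cases run on the same 256 mm thorax rasterized at 2 mm
(`tracking_sim_settings()`), with tumor diameters of 18–28 mm and motion
amplitudes of 8–18 mm, the range of the clinical lung-SBRT cohort this
experiment mirrors, and with rib/spine at cortical-bone attenuation
(0.48/0.96 per cm, HE/LE ratio still exactly 0.5). At the coarse 4 mm
synthesis grid, with the milder default bone, the comparison is degenerate:
a 10 mm tumor is 2.5 px wide, neither arm can track it, and both arms score
identically. With the clinical-scale world the mechanism under study
appears: the single-energy tracker locks onto rib shadows the tumor crosses
while the bone-suppressed arm follows the tumor.

## What a green test does and does not establish

The phantom reproduces the geometric mechanism that makes SE tracking hard —
a moving soft-tissue sphere behind static high-contrast rib arcs — but none
of the confounders of clinical fluoroscopy: noise, scatter, beam hardening,
anatomical variability, cardiac motion, detector blur. Synthesis quality
targets (SSIM >= 0.99, PSNR >= 40 dB at desk scale) therefore certify that
the model has learned the simulated SE-to-DES mapping, not that it would
perform clinically; the tracking comparison certifies a direction of effect
(DES no worse than SE under rib overlap), not clinical effect sizes.

## Numerical choices and degenerate inputs

* Log floor 1e-8 before any logarithm (subtraction undefined at zero).
* Identity rotation short-circuits resampling, so it is bit-exact.
* NCC windows with zero energy score 0; all-constant frames retain the
  previous position (tie rule above).
* Histogram matching against a constant reference returns the constant.
* Registration falling below a similarity of 0.2 warns and returns the
  identity transform.
* PSNR of identical images reports `Inf` rather than a capped number.
* Seeds: one master seed fans out per stage via a documented integer hash
  (`derive_seed`), keeping every derived seed below 2^31.

## Known limitations

Parallel-beam geometry only (cone-beam divergence is not modelled); the
phantom's ribs do not move with respiration; the synthesizer is trained and
evaluated at one detector scale; and the clinical-adjustment path is
exercised only on synthetic stand-ins for clinical frames, since no public
fluoroscopy accompanies this package.
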