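# fluorodes

Markerless lung-tumor tracking on kV fluoroscopy degrades when rib shadows
overlap the tumor. Dual-energy subtraction (DES) imaging suppresses bone —
`ln I_DES = ln I_HE − ω·ln I_LE`, with `ω` chosen so the bone pathlength
cancels — but needs dedicated two-energy hardware. `fluorodes` implements
the simulation-to-synthesis alternative end to end, in R:

1. **Phantom** — a 4D digital thorax (torso, lungs, spine, curved ribs,
   a spherical tumor breathing with `A·sin²(π(p−1)/P)` over 10 phases),
   rasterized deterministically, with monoenergetic attenuation surrogates
   for 120/60 kVp where bone has `μ_HE/μ_LE = 0.5` exactly.
2. **Projection** — volume rotation `R = Rx(θ)Ry(φ)Rz(γ)` (couch/gantry
   angles) and parallel-beam DRRs, `I = I0·exp(−∫μ dl)`, noise-free.
3. **DES core** — weighted log subtraction (default `ω = 0.5`, the exact
   bone-cancelling weight for the default spectra), training-grid
   enumeration (the full protocol is 10 phases × 36 couch pairs × 100
   gantry angles = 36,000 pairs), and paired scale/crop augmentation.
4. **Residual U-Net** — SE→DES image synthesis, implemented from scratch
   (im2col convolutions in C++, backprop and Adam in R): MSE loss, learning
   rate 0.02 linearly decayed to 1e-4, per-image min-max normalization, and
   a global input→output residual so the network learns the bone-correction
   field.
5. **Clinical adjustment** — affine registration, histogram matching and
   5×5 median smoothing to pull foreign-domain frames toward the DRR
   appearance before synthesis.
6. **Tracking & evaluation** — NCC template matching (the energy-normalized
   form without mean subtraction), RMSE (mm), tracking success rate (TSR,
   strict 25%-of-motion-range rule), PSNR/SSIM, and paired bootstrap
   comparison of the SE and DES tracking arms.

The audience is researchers in image-guided radiotherapy who want a fully
reproducible, self-contained desk-scale testbed for DES-synthesis tracking
pipelines: every input is generated by code, and the package's central
correctness guarantee — DES with the bone-cancelling weight is pixel-wise
identical to a bone-free simulation — holds to machine precision.

## Worked example

```r
library(fluorodes)

# one fluoroscopy case: 22 mm tumor breathing 15 mm, anterior-posterior beam,
# simulated on the clinical-resolution tracking grid (128^3 @ 2 mm)
case <- case_config(theta = 0, phi = 0, gantry = 180, n_frames = 30,
                    cycles = 1, tumor_diameter = 22, amplitude = 15)
s <- simulate_case(case, tracking_sim_settings(),
                   energy_specs = cortical_energy_specs())
s$motion_range
#> [1] 14.96933

# track the tumor on the SE arm and on the analytic DES arm
rep_ <- run_tracking_comparison(list(case), tracking_sim_settings(),
                                B = 500, seed = 1,
                                energy_specs = cortical_energy_specs())
round(rep_$cases[, c("rmse_se", "rmse_des", "tsr_se", "tsr_des", "p_rmse")], 3)
#>   rmse_se rmse_des tsr_se tsr_des p_rmse
#> 1   8.181    2.595     30      80  0.004
```

The tumor crosses rib shadows mid-cycle: on the single-energy arm the NCC
tracker locks onto the static ribs (RMSE 8.2 mm; only 30% of frames inside
the 3.7 mm success threshold), while on the bone-suppressed DES arm it
follows the tumor (RMSE 2.6 mm, 80%; paired bootstrap p = 0.004). Ground
truth is the projected phantom tumor centroid, so these numbers are exact,
not contour-dependent.

The full workflow — generate 500 training pairs, train the depth-3
residual U-Net, evaluate on four held-out couch-angle cases — is what
`scripts/acceptance.R` runs (about 12 minutes on one CPU).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch at desk scale, the synthesis-quality summary of
the trained model on the four unseen couch-angle cases (9,28), (17,5),
(20,32), (25,21): `t1` is the minimum per-case SSIM and `t2` the minimum
per-case mean PSNR (8-bit scale, dB) between synthesized and analytic DES
images. All randomness derives from `--seed`.

## Documentation

The methods vignette (`vignettes/des-synthesis-methods.Rmd`) describes the
phantom's stated world, the projection and subtraction algebra, the network
and training protocol, every numerical choice (tolerances, tie-breaks,
degenerate inputs), and what a green test does and does not establish.
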