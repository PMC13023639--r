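# octseg

Lumen segmentation for intravascular optical coherence tomography (OCT)
cross-sections, built for researchers who need a fully inspectable,
dependency-light implementation of a radial-prior segmentation network — and
for anyone who wants to study its components (polar resampling, deformable
convolution, boundary-aware attention, compound overlap losses) with
oracle-verified numerics.

In an OCT cross-section the blood-filled lumen is a dark disk — typically
less than 3% of the frame — inside bright concentric wall layers, corrupted
by multiplicative Rayleigh speckle. `octseg` trains a segmentation model
whose parts mirror that physics:

- **RIM (radial intensity module)** — differentiable Cartesian→polar
  resampling (`r = 2·√((x−c_x)² + (y−c_y)²)/(D−1)`,
  `θ = atan2(y−c_y, x−c_x)/π`), circular depthwise convolution along θ, and
  channel attention `ω = σ(MLP(DCT(f_θ)))` over the first 16 DCT-II
  frequencies of the angular profile.
- **D-CFM (deformable cross-scale fusion)** — offsets
  `Δp = Conv(Concat(U(f_m), f_l))` drive a from-scratch deformable
  convolution (bilinear gather, differentiable in input, offsets and
  kernel), gated by a Sobel edge map `g = σ(Conv(S(f_l)))`.
- **BAM (boundary-aware attention)** — a Laplacian-of-Gaussian edge
  indicator `E = 1[|∇²G_σ ∗ f| > τ]` modulates queries in 7×7-window
  attention `Softmax(W_q(E⊙f) · W_k(f)ᵀ/√d) · W_v(f)`.
- **Composite loss** — `L = 0.5·L_Dice + 0.3·L_BIoU + 0.2·L_FT` with
  BoundaryIoU on 2-px-dilated boundary bands and Focal Tversky
  (α = 0.3, β = 0.7, γ = 4/3).
- **Metrics** — Dice `2TP/(2TP+FP+FN)`, IoU, and HD95 (95th-percentile
  boundary surface distance) in pixels and millimetres at 5 µm/px.

Everything differentiable — conv2d, bilinear grid sampling with coordinate
gradients, max-pool morphology, windowed attention, layer norm, the
reverse-mode tape and AdamW — is implemented inside the package (R + Rcpp),
with every backward pass checked against finite differences and every
non-trivial operation checked against an independent brute-force oracle in
the test suite. Clinical OCT data is not distributable, so a seeded phantom
generator (dark lumen, ramp-and-decay wall profile, unit-mean Rayleigh
speckle, the full augmentation pipeline) makes the whole pipeline trainable
and testable from code alone.

## Worked example

```r
library(octseg)

## one synthetic frame + ground truth
ph <- generate_phantom(phantom_params(image_size = 64), seed = 0)
mean(ph$mask)            # lumen fraction, e.g. 0.0195  (< 3% of the frame)

## a small dataset on disk, 80/20 split
octseg_simulate(100, size = 64, out = "ds64", seed = 1)

## train the full model at desk scale (~3 min on one CPU)
cfg <- train_config(lr = 3e-4, weight_decay = 0, batch_size = 4, epochs = 15,
                    lr_schedule = "cosine", augment = FALSE,
                    model_cfg = model_config(rim_n_theta = 180))
run <- octseg_train("ds64", cfg, out_dir = "run1")
run$best_val_dice        # e.g. 0.826

## evaluate
ev <- octseg_eval(run$model, "ds64", split = "val")
ev$aggregate$dice$mean    # 0.826
ev$aggregate$hd95_px$mean # 1.47  (pixels)
ev$aggregate$hd95_mm$mean # 0.0074 (mm at 5 um/px)

## predict masks for new frames
octseg_predict(run$checkpoint, Sys.glob("ds64/case_00*[0-9].png"), "preds")
```

The numbers above are from an actual run (seed 1): best validation Dice
0.826 with mean HD95 of 1.47 px on 20 validation phantoms, a model of about
1.3 M parameters. At 3–6 px lumen radii these scores sit within a few
points of the speckle noise ceiling — see the methods vignette
(`vignettes/octseg-methods.Rmd`) for that calibration and for every design
decision.

Ablation variants (`model_config(rim = FALSE, ...)` etc., or
`--ablate rim|dcfm|bam` on the command line) disable one module each while
keeping the rest of the decoder identical.

A command-line front-end lives at `inst/cli/octseg.R`:

```sh
Rscript inst/cli/octseg.R simulate --n 100 --size 64 --out ds64 --seed 1
Rscript inst/cli/octseg.R train    --data ds64 --out run1 --seed 1 --epochs 15
Rscript inst/cli/octseg.R eval     --checkpoint run1/checkpoint.rds --data ds64 --out run1/eval
Rscript inst/cli/octseg.R predict  --checkpoint run1/checkpoint.rds --images 'ds64/*[0-9].png' --out preds
```

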