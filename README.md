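# toothseg

Automatic segmentation and tissue classification of a single tooth in micro
computed tomography (MicroCT) volumes, with quasi-Monte Carlo volume
measurement and a synthetic tooth phantom for end-to-end validation.

## The problem and the method

Finite-element stress analysis of a tooth (e.g. for vertical root fracture
work) needs each voxel assigned to one of enamel, dentine or pulp. Doing this
by hand, slice by slice, is the accepted reference but is slow; doing it
automatically is hard because MicroCT scans of an extracted tooth are noisy,
tissue boundaries are weak, not every slice shows all three tissues, and the
bracket holding the tooth during the scan touches the tooth base with
tooth-like intensity.

`toothseg` implements a two-stage framework:

1. **3D GFRLS segmentation** (tooth vs. background). A level-set function
   φ, initialized to +1 inside a cuboid and −1 outside, evolves by

   ∂φ/∂t = spf(I) · α · |∇φ|,  spf(I) = (I − (c₁+c₂)/2) / max|I − (c₁+c₂)/2|,

   where c₁, c₂ are the mean intensities inside/outside the current surface
   under a regularized Heaviside H_ε(z) = ½(1 + (2/π)·arctan(z/ε)). After
   each Euler step φ is re-binarized to ±1 ("selective binary") and smoothed
   with a 3D Gaussian — the regularization that replaces signed-distance
   re-initialization. The signed pressure force makes the surface expand
   inside bright regions and shrink outside them, so one cuboid
   initialization suffices.

2. **Improved PCNN classification** (tissues inside the tooth). A
   pulse-coupled neural network lattice — feeding F(n) = e^(−αF·Δt)F(n−1) +
   S + V_F(M∗Y), linking L(n) = e^(−αL·Δt)L(n−1) + V_L(W∗Y), internal
   activity U = F(1+βL), dynamic threshold θ(n) = e^(−αθ·Δt)θ(n−1) +
   V_θ·Y(n−1) — with a *graded* hierarchical output in place of the classic
   binary step:

   ξ = U − θ,  Y = ξ / max(ξ) · k,

   which resolves k intensity tiers at once and is binned into classes by
   rounding. Enamel is removed by an automatic (Otsu) threshold before the
   PCNN classifies the dentine/pulp interior.

Structure volumes are measured by scattering deterministic 2D Halton points
(bases 2, 3) over each slice's bounding box and summing the hit-fraction
areas across the stack. Evaluation statistics include Dice similarity,
sensitivity, specificity, signed relative volume error, mean absolute
deviation (MAD) of paired volumes, and an absolute-valued correlation
coefficient.

All volumes are `(z, y, x)` arrays (slice index first) with 0-based voxel
coordinates in user-facing arguments and spacing in mm (default 1 mm
isotropic, the geometry of the scans this framework targets).

## Worked example

```r
library(toothseg)

# synthetic single-tooth MicroCT phantom with exact ground truth
ph <- phantom_generate(phantom_spec(rng_seed = 1))
ph$volume
#> <volume3d> 128 x 128 x 128 voxels (z, y, x)
#>   spacing: 1 x 1 x 1 mm, origin: (0, 0, 0)
#>   intensity range: [0, 1]

# segment + classify
res <- run_pipeline(ph$volume, pipeline_config(seed_point = c(64, 64, 64)))
res$labels
#> <label_volume> 128 x 128 x 128 voxels (z, y, x)
#>   background 1926464 voxels
#>   pulp       8180 voxels
#>   dentine    121072 voxels
#>   enamel     41436 voxels

# evaluate against the phantom truth (Halton volumes, overlap indexes)
metrics_report(res$labels, ph$labels, halton_config(n_points = 1e5))
#> <metrics_report>
#>  structure computed_mm3 true_mm3 relative_error      S   SENS   SPEC
#>       pulp         8180     7960       0.027708 0.9864 1.0000 0.9731
#>    dentine       121072   120483       0.004892 0.9959 0.9983 0.9935
#>     enamel        41434    41434       0.000000 1.0000 1.0000 1.0000
#> MAD: 270.0026 mm^3   CorrCo: 1.0000
```

Reading the report: each row compares one tissue's Halton-estimated volume in
the automatic labels against the same estimate on the ground-truth labels.
`S` is the Dice similarity (1 = perfect overlap; > 0.7 is conventionally
strong agreement); `SENS`/`SPEC` say how the overlap is achieved — here pulp
has `SENS = 1` but `SPEC = 0.97`, i.e. the automatic pulp is slightly too
large (it absorbs a thin rim of true dentine). The dentine volume runs ~0.5 %
high because the residual bracket stub inside the ROI has dentine-like
intensity. Enamel is exact on this phantom.

The package also ships the published nine-pair volume benchmark (three
structures × three cases) for five methods; the per-method MAD of volumes is
a desk-checkable worked example:

```r
tab <- reported_volume_table()
round(sapply(tab[c("ours", "fcm", "hca", "dbscan", "gmms")],
             volume_mad, true_ = tab$ground_truth), 2)
#>    ours     fcm     hca  dbscan    gmms
#>  728.30 1014.79 1569.15 1687.48 1004.46
```

## Command line

A thin launcher script is installed with the package:

```sh
TS=$(Rscript -e 'cat(system.file("cli", "toothseg", package = "toothseg"))')
$TS phantom --out vol.tif --truth truth.tif --shape 128 --seed 1
$TS run     --input vol.tif --output labels.tif --report report.json \
            --seed-point 64,64,64 --block-radius 48
$TS volume  --labels labels.tif --label enamel --halton-points 100000
$TS metrics --pred labels.tif --truth truth.tif --report metrics.json
```

Subcommands: `phantom`, `segment`, `classify`, `run`, `volume`, `metrics`;
`--config file.yaml` supplies defaults that explicit flags override. Exit
codes: 0 success, 2 invalid arguments/config, 3 I/O failure.

## Package layout

- `R/volume.R`, `R/image_io.R` — `volume3d` / `label_volume` containers;
  TIFF, NIfTI, PNG-directory and raw readers/writers; config I/O.
- `R/gfrls.R` — level-set segmentation (`gfrls_segment()` and its parts).
- `R/pcnn.R` — PCNN dynamics and the hierarchical graded output
  (`pcnn_run()`, `labels_from_output()`).
- `R/pipeline.R` — the end-to-end framework (`run_pipeline()`).
- `R/metrics.R` — Halton volume estimation and evaluation statistics.
- `R/phantom.R` — the synthetic tooth phantom.
- `R/tables.R` — the published volume benchmark table.
- `vignettes/toothseg-methods.Rmd` — models, parameter rationale, design
  decisions, limitations.
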