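# lamina3d

Quantitative, unbiased 3D shape analysis of the **nuclear lamina** in
single-channel confocal z-stacks.

The nuclear lamina — a 30–100 nm intermediate-filament meshwork lining the
inner nuclear membrane — deforms early during changes of cell fate such as
apoptosis: it invaginates into the nuclear interior and lamin proteins
accumulate locally. Those changes are visible in live-cell confocal stacks
of GFP-tagged lamin long before the lamina breaks down, but "looks
distorted" is not a measurement. `lamina3d` segments the lamina surface
and reduces each cell to three voxel-size-independent shape descriptors
that support statistical classification of cell populations (for example,
untreated mesenchymal stem cells versus cells with activated caspase-8).

## Method

For a recorded stack *i(x, y, z)* with axial pitch ≈160 nm and lateral
pitch ≈60 nm:

1. **Isotropization.** Linear resampling to the lateral pitch, then lateral
   Gaussian blurring with σ<sub>r,blur</sub> = √(σ<sub>z</sub>² −
   σ<sub>r</sub>²) — with the Gaussian PSF model σ<sub>r</sub> = 62 nm,
   σ<sub>z</sub> = 190 nm this is 180 nm — so sampling *and* blur become
   isotropic.
2. **Segmentation** by 3D unsharp masking with a locally adaptive
   threshold:

   i<sub>um</sub> = i<sub>iso</sub> − (α·i<sub>blur</sub> + β),  mask = [i<sub>um</sub> ≥ 0]

   where i<sub>blur</sub> is a heavy anisotropic smoothing (σ<sub>L</sub> =
   60 nm lateral, σ<sub>A</sub> = 900 nm axial), α = 0.9, and β =
   max(i<sub>blur</sub>)/30 (i.e. transition intensity I<sub>c</sub> =
   β/(1−α) = max/3, set low because Poisson noise grows with intensity).
   A morphological closing with a digital sphere of radius 2.7 voxels
   (81 offsets) repairs holes without closing the nuclear interior.
3. **Measurement** over the mask voxels:
   * **i<sub>average</sub>** — mean of the 4σ-clipped, [0, 1]-normalized
     intensities;
   * **i<sub>skewness</sub>** — third standardized moment of the same
     distribution;
   * **K<sub>naaGc</sub>** = A<sub>CH</sub> · mean |κ₁κ₂| — the convex-hull
     normalized average absolute Gaussian curvature, computed from Gaussian
     derivative filters (σ<sub>g</sub> = 3 voxels) with surface normals
     from the gradient structure tensor (σ<sub>w</sub> = 7 voxels).
     Dimensionless, voxel-size independent, and equal to 4π for a perfect
     sphere — the package's calibration identity.
4. **Classification** with a Fisher linear discriminant (and a Gaussian
   quadratic variant), reported as a confusion matrix with binomial
   standard errors and exact one-sided significance against chance.

Because no public stacks exist for this assay, the package ships a phantom
generator: sub-resolution ellipsoidal shells with invaginations and
intensity hotspots, blurred by the anisotropic Gaussian PSF and corrupted
by Poisson noise, with exact ground truth. The methods vignette
(`vignettes/lamina-quantification.Rmd`) documents every parameter, the
numerical choices, and what phantom tests do and do not demonstrate.

## Worked example

Generate one control and one apoptotic-like phantom cell, segment and
measure both:

```r
library(lamina3d)

ctrl <- generatePopulation(1, "control",   seed = 11)[[1]]
apo  <- generatePopulation(1, "apoptotic", seed = 22)[[1]]
rbind(measureCell(ctrl$stack, cellId = "control"),
      measureCell(apo$stack,  cellId = "apoptotic"))
```

```
    cell_id i_average i_skewness  K_naaGc mask_voxels A_CH_nm2 excluded_voxels usable
1   control 0.5060526 -0.3912803 22.56637       67051 34822383              22   TRUE
2 apoptotic 0.3017795  1.0619029 27.73393       62220 33462967             139   TRUE
```

The apoptotic-like cell has lower average normalized intensity (its
hotspots stretch the normalization range), positive skewness (a bright
tail), and higher normalized curvature (invaginations bend the surface).
`usable` is the segmentation QC verdict (one dominant connected component
enclosing a cavity).

The full synthetic study — 20 cells per class, segmentation, measurement,
two-feature Fisher classification, scatter plot with the decision line —
runs in a few minutes on one CPU:

```r
res <- demoSynthetic(seed = 1, outDir = "demo_out", nPerClass = 20)
res$confusion
#> Confusion matrix (rows: predicted, cols: true; resubstitution ):
#>            
#>             apoptotic control
#>   apoptotic        20       0
#>   control           0      20
#>   apoptotic: 100% +/- 0% correct (exact one-sided binomial p = 9.54e-07)
#>   control: 100% +/- 0% correct (exact one-sided binomial p = 9.54e-07)
```

## Command line

```sh
Rscript inst/scripts/lamina3d.R segment  --in stack.tif --spacing 162.8,52.6,52.6 --out mask.tif
Rscript inst/scripts/lamina3d.R measure  --stack stack.tif --spacing 162.8,52.6,52.6 --out features.csv
Rscript inst/scripts/lamina3d.R classify --features features.csv --pair K_naaGc,i_average
Rscript inst/scripts/lamina3d.R demo     --seed 1 --out-dir demo_out
```

Defaults for every parameter are bundled in
`inst/config/paper_defaults.yaml`.
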