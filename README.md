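# octedema

Delineation of macular edema in retinal OCT B-scans by a two-step joint
model: bioinspired image enhancement followed by region-based level-set
segmentation, with a seeded synthetic phantom generator so the whole
pipeline is testable without clinical data.

Macular edema — fluid pooling in the macula, the leading sight-threatening
complication of retinal vein occlusion — shows on an OCT B-scan as dark
hypo-reflective cavities enclosed in the bright retinal band. Automatic
delineation is hard because OCT speckle is multiplicative:
`I = S · N_s + N_b`, with unit-mean speckle `N_s` and additive background
noise `N_b`. The package addresses this for ophthalmic image-analysis
researchers and tool builders in two steps.

**Step 1 — enhancement** (`enhance()`):

1. Gaussian filtering (5 × 5, unit-sum discrete kernel) suppresses speckle;
2. a global structure-transfer filter restores edges by solving the
   screened-Poisson system
   `(λA + Dxᵀ Dx + Dyᵀ Dy) O = λ I + Dxᵀ V^h + Dyᵀ V^v`
   for the output `O`, where `(V^h, V^v)` is a guidance gradient field taken
   from the smoothed original image (sparse Cholesky, residual ≤ 1e-8);
3. single-scale Retinex, `R = ln I − ln(G_c ∗ I)` with a unit-sum Gaussian
   surround, boosts contrast and turns residual multiplicative speckle
   additive.

**Step 2 — segmentation** (`segment()`): an SBGFRLS level set
(selective-binary, Gaussian-filtering-regularized) evolves under the signed
pressure force

```
SPF(I) = (I − (c1+c2)/2) / max|I − (c1+c2)/2| ∈ [−1, 1]
φ     ← φ + Δt · α · SPF(I) · |∇φ|
```

where `c1`, `c2` are the mean intensities inside/outside the zero level.
Each iteration re-binarizes φ to ±1 and smooths it with a Gaussian instead
of re-initializing. The converged labeling is canonicalized so the final
masks are bit-identical regardless of the initial contour. The retina mask
is the filled largest positive component; edema cavities are recovered as
hypo-reflective components strictly inside it.

`cnr()`/`enl()` quantify image quality (contrast-to-noise ratio, equivalent
number of looks), and `confusion()`/`scores()` produce the seven pixelwise
segmentation scores (accuracy, precision, sensitivity, specificity, Dice,
IoU, Cohen's kappa) against ground truth.

## Worked example

```r
library(octedema)

pair <- generate_phantom(phantom_spec(seed = 3))  # 128 x 256, speckle shape 4
enh  <- enhance(pair$image)
seg  <- segment(enh)
seg
#> segmentation_result: 21 iterations (converged), retina 17199 px, edema 1924 px
```

Or as one configured, manifest-writing run:

```r
res <- run_pipeline(pipeline_config(phantom = list(seed = 3)))
res
#> pipeline_result
#> segmentation_result: 21 iterations (converged), retina 17199 px, edema 1924 px
#>   CNR 2.228 -> 7.216, ENL 6.6 -> 360.6
#>   Dice: retina 0.9835, edema 0.9644
```

Reading the numbers: the level set converged in 21 iterations; enhancement
raised the contrast-to-noise ratio of the retina-band ROI from 2.23 to 7.22
(≈ 5 dB) and the equivalent number of looks from 6.6 to 361 (smoother
speckle); the segmented retina and edema masks overlap the ground truth
with Dice 0.98 and 0.96 — both far above the 0.70 conventionally labelled
excellent agreement.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/oct-edema.R", package = "octedema"))')
Rscript $CLI simulate --out-dir sim
Rscript $CLI enhance sim/image.png --out enhanced.png
Rscript $CLI segment enhanced.png --out-retina r.png --out-edema e.png
Rscript $CLI evaluate --pred r.png --truth sim/retina_mask.png
Rscript $CLI run --config config.yaml
```

Subcommands exit 0 on success, 2 on configuration errors (unknown YAML keys
are rejected, not ignored), 3 on stage failures.

## Documentation

The methods vignette (`vignettes/joint-model.Rmd`) documents the model and
its assumptions, every tunable parameter with its default and rationale,
what the phantom generator does and does not emulate, numerical
conventions, and known limitations.
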