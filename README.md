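# moorgb

Tumor segmentation for B-mode ultrasound images in R.

Ultrasound lesions are notoriously hard to delineate automatically —
speckle, low SNR, intensity inhomogeneity, and acoustic shadowing defeat
purely region-based and purely edge-based methods alike.  `moorgb`
implements a compound pipeline for radiologist-style workflows: the user
supplies only a rectangular region of interest with the lesion roughly
centered (the *tumor-centered image*, TCI), and the package does the rest.

## Method

The segmenter is a minimum-spanning-tree region-merging algorithm: pixels
are graph vertices, edges join neighbours with weight |ΔI|, and two
regions merge when

    Dif(C1, C2) = |μ(C1) − μ(C2)|  ≤  min_i ( σ(C_i) + τ(C_i) ),
    τ(C) = (k/|C|) · (1 + (μ(C)/σ(C)) / α)

Its two parameters `(k, α)` are tuned per image by particle swarm
optimization maximizing

    F_O = a·V_B/f_B − b·V_W/f_W + c·G_A/f_A        (a, b, c = 0.3, 0.3, 0.4)

where `V_B` is the between-class variance of the candidate tumor region
against its neighbours, `V_W` the arctan-damped within-class variance over
the region's area fraction, `G_A` the mean Sobel gradient along the
region's boundary, and `f_B, f_W, f_A` are normalization factors fixed
once from the initial swarm.  The winning region is refined by
morphological opening/closing (5×5 elliptical kernel) and scored, when a
ground-truth mask exists, by averaged radial error (ARE, 180 rays) and
volume fractions (TPVF/FPVF/FNVF).

A deterministic speckle-phantom generator (`phantom_suite()`) provides
synthetic lesions with known truth masks, so the entire pipeline is
testable without clinical data.

## Worked example

```r
library(moorgb)

suite <- phantom_suite(1, "easy", seed = 1)          # 128x128 phantom + truth
cfg <- pipeline_config(pso = swarm_config(n_p = 50, t_max = 60, seed = 1))
res <- run_moorgb(suite[[1]]$image, cfg = cfg, truth = suite[[1]]$truth)
res
#> moorgb: optimal k=3740.0 alpha=0.6283, mask 1894 px, 9 generations
#> ARE 13.04%  TPVF 97.57%  FPVF 25.80%  ARE ...  (180 rays)
res$metrics
#> ARE 13.04%  TPVF 97.57%  FPVF 25.80%  FNVF 2.43%  (180 rays)
```

The optimizer settled on a large `k` (aggressive merging) with a small
`α`, the refined mask covers 97.6% of the true lesion (TPVF) with a 25.8%
over-reach relative to the lesion area (FPVF), and the mean radial
deviation between the segmented and true contours is 13% of the lesion
radius (ARE).

A command-line front end lives in `inst/cli/moorgb.R`:

```sh
Rscript inst/cli/moorgb.R phantom --n 3 --difficulty easy --seed 1 --out phantoms/
Rscript inst/cli/moorgb.R segment --input phantoms/phantom_001.pgm \
    --truth phantoms/truth_001.pgm --out result/
Rscript inst/cli/moorgb.R evaluate --truth phantoms/truth_001.pgm --seg result/mask.pgm
Rscript inst/cli/moorgb.R sweep --n 5 --seed 1 --out sweep/
```

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch — generating
seeded phantoms, optimizing `(k, α)` per image, and measuring the
resulting masks against their truth — and writes a JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/moorgb-methods.Rmd`) documents the model
and its assumptions, every tunable parameter with its default and
rationale, the numerical conventions (tie-breaking, σ = 0 handling,
sub-pixel contour localization), what the phantom generator does and does
not emulate, and known limitations.
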