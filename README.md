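# trichromequant

Quantitative histomorphometry of Masson's-trichrome-stained skin from
brightfield photomicrographs.

Masson's trichrome marks collagen blue–green (aniline blue) and
muscle/cytoplasm/keratin red–pink (Biebrich scarlet–acid fuchsin). Grading
collagen content by eye is subjective; this package implements a fully
reproducible measurement pipeline for it, aimed at researchers quantifying
dermal collagen (wound healing, fibrosis, aging models) from standard 24-bit
RGB micrographs.

## The method

Stains mix linearly in optical density (Beer–Lambert):
`OD_c = -log10((I_c + 1) / 256)` per channel `c`. Each dye is characterised
by a unit *stain vector* — its RGB absorbance direction — estimated from a
region of interest dominated by that dye (dermal collagen; panniculus
carnosus muscle). With the two vectors `v1, v2` and their unit cross product
`v3` as rows of `M`, the per-pixel dye concentrations solve

```
OD = t(M) %*% c        =>        c = solve(t(M), OD)
```

Each concentration plane is rendered as an 8-bit *stain-amount* channel,
`255 - round(255 * 10^(-c))`, so larger values mean more stain. The
measurement pipeline is then:

1. **Tissue mask** — blur the collagen channel (Gaussian, σ = 2 px),
   auto-threshold it with the iterative-intermeans ("Default") method with
   black pixels ignored, and consolidate with a binary closing (3×3, 1
   iteration). This closes the natural cracks between collagen bundles.
2. **Per-stain segmentation** — auto-threshold each unblurred stain channel
   the same way, then AND it with the tissue mask.
3. **Features** — per stain: calibrated areas (default 473 px/mm, so
   `mm² = px / 473²`), thresholded-to-mask area ratio (the collagen-density
   readout), and gray-value statistics inside the AND region: mean, median,
   SD, min, max, skewness `m3/m2^1.5` and excess kurtosis `m4/m2² − 3`.
4. **Statistics** — per feature, a Shapiro–Wilk gate (normal iff p > 0.05)
   selects either a pooled two-sample t-test (both groups normal) or the
   Mann–Whitney U test; paired features are related by OLS regression with
   R². Summaries are mean ± SD or median [IQR] accordingly.

A synthetic trichrome scene generator (`generate_scene()`) builds skin-like
images — background, epidermis, a dermis of collagen bundles with cracks and
follicular voids, a red muscle band — from known concentration fields, so
the whole pipeline is validated against exact ground truth.

## Worked example

```r
library(trichromequant)

sc <- generate_scene(scene_params(width_px = 600, height_px = 440,
                                  collagen_fill = 0.5, seed = 1))
fr <- extract_features(sc$image, image_id = "demo")
fr
#> <trichrome_features> demo  (thresholds: mask=80, blue-green=131, red-pink=137)
#> # A tibble: 2 × 13
#>   image_id stain      mask_area_mm2 thresh_area_mm2 thresh_to_mask_pct
#>   <chr>    <chr>              <dbl>           <dbl>              <dbl>
#> 1 demo     blue-green         0.444          0.222               50.0
#> 2 demo     red-pink           0.444          0.0286               6.45
sc$truth$true_collagen_fraction_of_dermis
#> [1] 0.4951126
```

The scene was built with half its dermis occupied by collagen bundles; the
pipeline measures a blue–green thresholded-to-mask ratio of 50.0% against a
ground-truth fraction of 49.5%. The per-image log line reports the three
auto-thresholds chosen (mask, blue–green, red–pink channels), `mask_area_mm2`
is the calibrated connective-tissue area, and the paired record
(`fr$paired`) gives the red-to-blue area ratio (12.9% here — collagen
dominates, as it should in dermis).

Batch use from a shell (see `inst/cli/trichrome-quant`):

```sh
trichrome-quant simulate --out fixtures --suite
trichrome-quant run --out results fixtures/scene_fill50_seed1.png fixtures/scene_fill70_seed1.png ...
trichrome-quant compare --features results/features.csv --out report
```

`compare` writes a Markdown table with one row per feature: per-stain
summary, the gated test used, and its p-value.

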