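---
title: "Methods: trichrome histomorphometry, model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trichrome histomorphometry, model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trichromequant)
```

## The physical model

Brightfield dyes attenuate light multiplicatively, so stain amounts add in
optical density rather than intensity. We use the offset form
`OD = -log10((I + 1)/256)`, which keeps OD finite at `I = 0` and caps it at
`log10(256) ≈ 2.408` per channel. The offset is the standard practice of
color-deconvolution tools; its price is a slightly nonuniform OD grid — the
spacing between adjacent 8-bit levels grows as `0.434/(I + 1)`, i.e. from
~0.0017 OD near white to ~0.3 OD near black. This matters below.

Each dye is a unit vector of per-channel optical densities. A blue-green
dye absorbs mostly red light, so its R component is the largest
(blue-green ≈ (0.8001, 0.4070, 0.4407); red-pink ≈ (0.4311, 0.7154,
0.5498) — the package defaults, `trichrome_basis()`). Unmixing solves the
3×3 system per pixel with the unit cross product as the third, residual
axis. Negative concentrations (noise cross-talk) are preserved in the float
result and clipped only when rendering the 8-bit channel: this keeps
`deconvolve()` exactly linear and invertible, which the round-trip tests
rely on.

### ROI vector estimation

How a vector should be derived from a user-drawn ROI is genuinely open
(mean OD vs. first principal component). We use the mean OD, normalised to
unit length: it is robust at the small ROI sizes users draw, has no sign
ambiguity, and for a region dominated by one dye the two estimators agree
to first order. A blank (white) ROI has near-zero mean OD and is rejected
(`DegenerateROI`) rather than normalised into noise.

### Channel polarity

Whether stain channels should be stored as transmittance (dark = much
stain) or stain amount is ambiguous in common practice. We store *stain
amount*, `255 - round(255·10^(-c))`, so larger = more stain. This is the
convention under which strongly stained regions report a maximum gray value
of 255 and "higher intensity" reads as "more dye", which is how the
downstream statistics are interpreted.

## Segmentation

The tissue mask is built from the collagen channel: Gaussian blur
(σ = 2.0 px, reflective boundaries), iterative-intermeans auto-threshold
with bin 0 removed ("ignore black"), binary closing (3×3 square, 1
iteration). Parameters and their roles:

* **σ = 2.0 px** — wide enough to bridge the unstained cracks between
  collagen bundles before thresholding, narrow enough not to bleed the
  dermis into background.
* **"ignore black"** — unstained pixels land in bin 0 of the stain-amount
  histogram; removing them stops the (often dominant) background mass from
  dragging the intermeans threshold toward zero.
* **Closing, 3×3, 1 iteration** — consolidates remaining pinholes. The
  element size and iteration count are the common defaults of
  morphological post-processing; both are exposed as arguments.

The intermeans threshold iterates `t ← round((μ_≤t + μ_>t)/2)` from the
midpoint of the occupied range; rounding is half-up (`floor(x + 0.5)`),
ties therefore break upward deterministically. Foreground is strictly
`value > t`. A histogram with fewer than two occupied bins (e.g. an
all-white image) raises `DegenerateHistogram`; in the full pipeline a
degenerate *stain* channel is interpreted as "this stain is absent" and
yields an empty thresholded region, while a degenerate *mask* channel is a
hard error (there is no tissue to measure).

Per-stain thresholds are computed on the whole-image histogram of the
unblurred channel and then ANDed with the mask — thresholding first,
restricting second. Computing the threshold inside the mask instead is
supported (`threshold_within_mask = TRUE`); on our synthetic scenes the two
orderings give thresholds within a few gray levels of each other.

**Border conventions.** The blur reflects the image at its edges. For
morphology, dilation treats outside-image as background; the erosion inside
the closing treats it as foreground. With background-padded erosion a
closing would shave mask pixels touching the image border, violating the
defining property `closing(X) ⊇ X`; foreground-padded erosion preserves it
everywhere, which our property tests assert including borders.

## Features and calibration

Areas are `px / px_per_mm²` with `px_per_mm = 473` by default (a 4×
objective setup where 1 mm spans 473 px). Halving the calibration
quadruples areas and leaves every ratio and intensity statistic unchanged
(tested). Intensity statistics follow the conventions of interactive
measurement tools: SD uses the `n − 1` denominator while skewness and
excess kurtosis use population moments (`m3/m2^1.5`, `m4/m2² − 3`); the
median of an even-sized region is the mean of the central pair; shape
statistics of a constant region are `NaN`, not an error.

## Statistics

The two-group comparison is normality-gated: Shapiro–Wilk (Royston's
approximation, via `stats::shapiro.test`) on each group, "normal" strictly
`p > 0.05` (a p of exactly 0.05 counts as non-normal); both normal → pooled
two-sample t-test (Welch by flag), otherwise Mann–Whitney U. Groups are
summarised as mean ± SD when normal, median [IQR] otherwise, with quartiles
by linear interpolation. A constant group, for which Shapiro–Wilk is
undefined, is treated as non-normal — the rank test remains valid there.

Mann–Whitney p-values are exact by full enumeration of label assignments
(valid under ties, using midranks) when the combined sample size is ≤ 12,
and otherwise use the normal approximation with continuity and tie
correction. The cutoff is where enumeration (≤ 924 subsets) is instant and
the approximation is still rough; above it the approximation agrees with
the exact test to well under 0.02 in our simulations. Two-sided throughout.

No multiple-testing correction is applied across the feature table — the
report says so in its footer — and cohort images are treated as
independent. Both choices mirror how such feature tables are typically
analysed; if several images per animal are analysed, the p-values are
anti-conservative and a hierarchical model would be needed (out of scope).

## The synthetic scene generator

`generate_scene()` emulates the cross-section geometry the pipeline
targets: background, thin red epidermis, a dermis band (40% of height by
default) of collagen bundles, elliptical unstained follicular voids, and a
red muscle band (10%). Bundles are a Gaussian random field (correlation
length 2 px) cut at the `1 − collagen_fill` quantile of the stainable
dermis, so the fill fraction is controlled essentially exactly; thin
random-walk polylines carve unstained cracks. Bundle concentration is
`peak_blue_conc · (0.15 + 0.85·u)` with `u` the normalised texture — the
*peak* (default 3.0) is attained only in the densest cores, so the 8-bit
channel saturates at 255 there while the channel median stays well below
it, giving the broad, platykurtic intensity distribution real collagen
staining shows. The inter-bundle matrix carries weak blue uptake (0.2
concentration units) and diffuse red (0.08) plus stronger red speckle (6%
of dermis at 1.6); both concentration fields are composed to RGB through
the same Beer–Lambert model the pipeline inverts, then Gaussian sensor
noise (SD 2 gray levels) is added in RGB space and clipped — a sensor
model, deliberately *after* composition.

The two-threshold mechanism works on these scenes exactly as the protocol
intends: after blurring, the dermis (bundles + weak matrix) is one
intensity population well above background, so the mask covers the whole
band; unblurred, the bundles separate from the matrix, so the per-stain
threshold isolates them. Across fills 0.3–0.7 and ten seeds the measured
blue thresholded-to-mask ratio tracks the true fill within about one
percentage point.

What the generator does **not** emulate: nuclei/hematoxylin, out-of-focus
blur, uneven illumination, stain gradients, real bundle anisotropy, or
JPEG artefacts. Passing recovery tests therefore validate the pipeline's
*logic and numerics*, not its robustness to every acquisition artefact.

## Known numerical limitations

* **8-bit dynamic range bounds unmixing accuracy.** Per-channel OD is
  capped at 2.408, but two dense stains can sum to OD ≈ 3.7 on a channel;
  such pixels render as 0 and their concentrations are unrecoverable. Even
  below the cap, the OD grid step near black (~0.1–0.3) times the ≈2–3×
  amplification of this rather collinear stain pair (v1·v2 ≈ 0.88) limits
  recovery: quantization-exact to ±0.02 only up to concentrations of about
  0.75 per stain; ±0.035 at 1.0; divergent beyond ~1.5 on both stains at
  once. This is physics of saturated 8-bit brightfield, not an
  implementation artefact; deeply stained pixels should be interpreted as
  "saturated", not quantified.
* **Saturation leaks between channels under noise.** At near-black pixels,
  ±2 gray levels of sensor noise is ±0.3 OD, and unmixing amplifies it into
  spurious concentration in the *other* stain. The generator's broad
  concentration spread keeps this leakage small, but heavily overstained
  real slides would show it.
* **Problem sizes.** Validation suites run on 600×440 scenes (recovery,
  30-seed grids) and one native 1832×1321 scene (timing, saturation); these
  sizes make the texture and blur scales identical to full frames while
  keeping the suites quick. Scene structure is scale-free above ~200 px.

## Error taxonomy

All domain errors are classed conditions (`tq_error_*`): empty/degenerate
ROIs, collinear vectors, singular bases, degenerate histograms, dimension
mismatches, too-small samples, degenerate regressors, too-few images. The
CLI maps them to nonzero exit codes; batch runs log per-image failures and
continue.
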