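# hkls — hybrid hierarchical K-means + level-set skin lesion segmentation

`hkls` delineates melanocytic skin lesions (nevi, melanomas) in
dermoscopic and standard clinical photographs.  It is aimed at
quantitative-dermatology and medical-image-analysis work where a lesion
border is needed before any downstream measurement — diameter, border
irregularity, area agreement between observers — and where training data
for learned segmenters is scarce.

## Method

The pipeline has three stages:

1. **Chromaticity fusion preprocessing** — sRGB → CIE L\*a\*b\* (D65);
   the lightness channel is discarded and the histogram-equalized a/b
   chromaticity channels are fused into a scalar substrate
   `gray = (a_eq + b_eq)/2` that is largely insensitive to illumination
   artifacts.  A 5×5 maximum filter removes hair and ruler marks;
   near-black vignetted frames are excluded as the complement of the
   largest non-dark blob.

2. **Hierarchical K-means (HK) initialization** — two-level top-down
   Lloyd K-means (squared Euclidean, K₁ = 2 then K₂ = 3 on the darker,
   lesion-candidate cluster; 20 iterations per level) produces a coarse
   lesion region and its bounding rectangle.

3. **Distance-Regularized Level Set Evolution (DRLSE)** — from the
   rectangle, the contour shrinks onto the lesion border under

   φ ← φ + Δt [ μ div(d_p(|∇φ|)∇φ) + λ δ_ε(φ) div(g ∇φ/|∇φ|) + α g δ_ε(φ) ]

   with double-well regularization potential p (wells at |∇φ| = 0 and 1;
   no reinitialization ever), edge indicator g = 1/(1+|∇(G_σ∗I)|²), and
   the published operating point μ = 0.02, λ = 5, ε = 1.5, c₀ = 3,
   Δt = 8, σ = 1.5, α ∈ {3, 5} by an if-then rule on the initial region
   size.  The field is thresholded at 80 (8-bit scale) and cleaned by
   hole filling, 5-px square erosion and Delaunay boundary smoothing.

Evaluation utilities cover the standard agreement statistics: accuracy,
sensitivity, specificity, Jaccard, Dice, F-measure, boundary Hausdorff
distance (raw and diagonal-normalized), Bland–Altman limits of agreement
and area regression.  A seeded synthetic dermoscopy generator (perturbed
elliptical lesion + hair/vignette/ruler/illumination/noise artifacts with
exact ground truth) makes the whole package testable with no external
data.

## Worked example

```r
library(hkls)

g   <- generate_image(synthetic_spec(seed = 3))   # image + ground truth
res <- segment_lesion(g$image, truth = g$mask, image_id = "demo")
m   <- res$record$metrics
sprintf("dice %.3f | jaccard %.3f | accuracy %.3f | sensitivity %.3f | HD(norm) %.4f",
        m$dice, m$jaccard, m$accuracy, m$sensitivity, m$hausdorff_norm)
#> "dice 0.970 | jaccard 0.942 | accuracy 0.989 | sensitivity 0.942 | HD(norm) 0.0083"
res$record$alpha              #> 5    (area rule chose the stronger shrink force)
res$record$drlse_iterations   #> 600
```

`dice`/`jaccard` are overlap fractions against the ground-truth mask,
`accuracy` the fraction of pixels labeled correctly, and `HD(norm)` the
largest boundary disagreement as a fraction of the image diagonal — here
about 3 px on a 256×256 frame.  `write_mask()` saves the result as a
0/255 PNG; `write_results()` emits a CSV row per image plus a JSON
configuration sidecar sufficient to re-run deterministically.

A command-line front end is installed with the package
(`system.file("cli/hkls.R", package = "hkls")`) with subcommands `synth`,
`segment`, `evaluate` and `sweep` (the cluster-count selection experiment
over K₁ × K₂).

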