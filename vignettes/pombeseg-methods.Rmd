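---
title: "Segmenting fission-yeast cells in bright-field images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting fission-yeast cells in bright-field images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pombeseg)
```

## The problem

Transmitted-illumination (bright-field) images of *Schizosaccharomyces
pombe* show each rod-shaped cell as a dark membrane ring around an interior
that is slightly brighter than the background — but only when the specimen
sits on the in-focus side of the objective's focal plane. Defocus flips
this contrast: on the other side of focus, interiors darken and membranes
brighten, both roughly mirrored about the background intensity. When the
slide is tilted relative to the focal plane, *both* polarities coexist in
one field of view, separated by a line where the specimen plane crosses the
focal plane. High-content screens produce thousands of such images with
varying focus, lighting and contrast; segmentation must survive all of it
without per-image tuning.

`pombeseg` implements a pipeline for this setting: nuclear-fluorescence
channels (when present) anchor a focus-gradient correction; adaptive
thresholds classify pixels into background, cell interior, membrane and
ambiguous classes; a distance-transform procedure resolves the ambiguous
class; gradient-vector-flow (GVF) snakes evolve interior components to the
cell boundaries; and machine-learning validators discard merged, partial
and artifactual contours.

## Region detection and shading correction

Every channel is first flattened by subtracting its disk-kernel mean filter
(radius 40 px, replicate padding so the frame border is not darkened). The
background is the flat part of the bright-field image: pixels whose Sobel
gradient magnitude falls below the Otsu threshold of the gradient image.
Two details matter in practice:

* cell interiors are also locally flat, so the raw low-gradient mask is
  filtered to connected components covering at least 1% of the frame —
  interiors are enclosed by the high-gradient membrane band and fall away
  as small components;
* nuclei detected in the fluorescence channels (Otsu threshold, union over
  channels, components under 20 px^2 discarded) are subtracted from the
  background so the two region means are computed on disjoint supports.

The nucleus mean μ_N and background mean μ_B of the bright-field channel
summarize the field's contrast state. Without usable fluorescence the
pipeline sets μ_N = μ_B and skips focus correction entirely.

## Focus-gradient correction

Within moderate defocus, the nucleus-minus-background intensity difference
is approximately linear in the defocus distance z, and the membrane and
interior intensities are approximately symmetric about μ_B. Assuming a flat
(but tilted) specimen plane, z is modelled as a bilinear plane
`z(x, y) = a + b·x + c·y`, fitted by ordinary least squares to the nucleus
centroids with `z_i = mean(nucleus_i) − μ_B`. Where the fitted plane is
negative, intensities are complemented about the background mean,
`j = 2 μ_B − i`: an involution whose fixed point is μ_B, so intensity stays
continuous across the z = 0 line wherever the local intensity is near
background. A global affine map anchored at μ_B then sets the
nucleus-background contrast to a fixed target Δ (default 0.15 × the input
dynamic range, one constant for a whole dataset); when μ_N < μ_B the map's
negative scale also complements a globally inverted image.

The criterion for "has a focus gradient" is not prescribed by the model, so
the package decides it as: the fitted plane must change sign within the
frame (otherwise there is nothing to complement) *and* explain at least
R² ≥ 0.3 of the nucleus-z variance (so that noise alone cannot trigger a
flip). Both are overridable (`focus_correction_mode = "on"/"off"`).

Known limitation, inherited from the plane model: cells straddling the
estimated z = 0 line are half-complemented and genuinely distorted. Their
contours tend to be flagged partial by the validator, trading recall for
precision near the line. Estimating the boundary by margin maximization
instead of least squares would likely help and is deliberately out of
scope.

## Pixel classification

On the corrected image, with B the detected background:

* membrane: `i < t_m`, where t_m is the Otsu threshold of the
  sub-histogram of pixels darker than μ_B ("adaptive threshold from all
  pixels darker than the background");
* interior: `i > μ_N` (strict; computed on the corrected image where
  μ_N = μ_B + Δ). Without fluorescence the interior threshold is instead
  the Otsu threshold of pixels brighter than μ_B, the symmetric
  construction to t_m;
* precedence on overlap: background, then membrane, then interior;
  remaining pixels are ambiguous.

Each class is smoothed by morphological close-opening with a radius-1
disk and isolated pixels are removed. The structuring element is the
diamond (4-neighbour) disk: the 3×3 box erases 2–3 px membrane rings at
diagonal orientations outright, while the diamond preserves them.
Pixels vacated by smoothing become ambiguous.

Ambiguous pixels are then resolved by iterated distance transforms: with
Euclidean distance maps D_b, D_c, D_m of the current background, interior
and membrane sets, an ambiguous pixel joins the background if
`D_b ≤ D_c` and `D_b < D_m`, the interior if `D_c < D_b` and `D_c < D_m`;
the maps are recomputed and the rule re-applied until the ambiguous set is
unchanged. Ties go to the background, and the membrane acts as a barrier:
pixels nearest to membrane survive all iterations and exit as membrane.
Only ambiguous pixels are ever relabelled, so the procedure terminates.
This watershed-like rule is a reconstruction from the documented intent of
the procedure; the exact inequalities are fixed and tested against an
independent step-by-step reference so results are reproducible.

## GVF snakes

The membrane edge map f is the smoothed (σ = 1 px Gaussian) indicator of
the membrane class, rescaled to max 1. The GVF field (u, v) minimizes

    E = Σ μ (|∇u|² + |∇v|²) + |∇f|² |(u,v) − ∇f|²

via the explicit diffusion–reaction iteration with time step bounded by
`dt ≤ 1/(4μ)`; the iteration is, exactly, gradient descent on the
discretized energy, which the test suite verifies against an independent
sparse-matrix implementation. μ = 0.8.

Initial contours are the boundaries of 8-connected interior components of
at least 50 px², resampled to ≈2 px vertex spacing. Each contour evolves
semi-implicitly: tension α = 0.03 and rigidity β = 0.2 enter through a
cyclic pentadiagonal system solved implicitly (weights λ1 = λ2 = 1,
dt = 1), and the external force is the GVF field sampled at the vertices by
bilinear interpolation. Two standard stabilizations are applied and
documented as the package's own choices:

* the sampled force is scaled by the field's maximum magnitude (unit-max
  normalization), making the step size comparable across images;
* only the component normal to the contour is kept. The tangential part
  merely reparameterizes a closed curve; on pixel-rough edge maps it
  drags vertices into local attractors and collapses the polygon.

Vertices are resampled every 10 iterations and clamped to the frame;
evolution stops after 200 iterations or when the largest displacement
falls below 0.05 px. Contours dropping below 8 vertices are flagged
degenerate and preset to the artifact verdict. Rasterization resolves
contested pixels smaller-contour-first.

## Contour validation

Ten fixed-order features are computed per contour: area, perimeter,
ellipse-moment eccentricity, solidity, major/minor axis lengths, mean
contour-band contrast (±1.5 px around the contour, minus μ_B), interior
contrast, border-contact fraction, and a has-nucleus flag. The two
intensity contrasts are divided by the background-to-membrane-threshold
gap; Otsu thresholds are affine-equivariant, which makes these features
comparable between corrected and uncorrected (no-fluorescence) images.

Three classifiers are trained on standardized features: RBF-kernel SVMs
(C = 1, γ = 1/10) for valid-vs-partial and valid-vs-merged, and a
classification tree for valid-vs-artifact (background/artifact detections
are rare and well separated, so a tree suffices). Verdict precedence:
degenerate/artifact first; then the deterministic boundary rule —
contours with more than 10% of vertices on the frame edge are partial
(boundary-truncated cells share the characteristics of partial
segmentations); then merged; then partial. The rule fires before the SVMs
because an extreme border fraction is out-of-distribution for the radial
kernels.

Because no manually labeled corpus ships with the package, training
labels come from the synthetic generator: the pipeline runs on generated
scenes and each contour is labeled by matching against the truth masks;
deliberately truncated rods, hulls of nearby cell pairs and background
blobs supply the error classes, each refined for 40 snake iterations so
their band statistics match application time. `train-validator --labels`
accepts a user-labeled CSV with the same columns for real data.

## The synthetic generator

Scenes emulate the screen's imagery: spherocylindrical rods (length 25–45
px for the short-rod preset, 60–110 px for the elongated
cell-cycle-arrest preset), membrane ring width 3 px and depth 30 below a
background of 128, interior lift +20, additive Gaussian noise σ = 5 on an
8-bit-like scale (dynamic range 255), Gaussian nucleus blobs (σ = 3 px,
amplitude 100) in the fluorescence channel for 80% of cells, minimum
clearance 4 px, rejection-sampled placement. Rasterization is ×4
supersampled so edges are anti-aliased and sub-pixel contour accuracy is
measurable. The instance truth mask of a cell extends to the membrane-ring
centerline: the ring images the cell wall, so the wall midline is the
natural cell extent — and the locus the snake converges to. Presets
include septating pairs (two abutting rods sharing a membrane wall) and a
focus-gradient preset whose plane inverts contrast over roughly a fifth of
the frame.

What the generator does not emulate: Poisson camera noise, the
point-spread function of real defocus (contrast flips are binary, not
graded), textured interiors, and crowding beyond the minimum-gap packing.
Passing the fixture benchmarks therefore demonstrates the pipeline's
mechanics — correction, classification, contour convergence, validation —
not performance on any particular microscope's data.

## Numerical choices and problem sizes

Defaults: GVF 80 iterations at dt = 0.9/(4μ); snakes 200 iterations at
dt = 1; contour spacing 2 px; shading radius 40 px; minimum cell area
50 px²; all exposed in `pipeline_config()`. The test suite and the
acceptance script run on 512×512 scenes with ~10–28 cells and on 256×256
scenes for unit tests; validator training uses five scenes (~300 labeled
contours). These sizes give stable statistics while keeping a full run in
the minutes range on one core. Determinism: scenes are pure functions of
their spec seed; validator cross-validation folds are seeded; the pipeline
itself contains no randomness, so identical seeds give bit-identical label
masks.
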