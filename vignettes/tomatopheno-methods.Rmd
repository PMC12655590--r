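---
title: "Methods: automated phenotyping of sectioned tomato fruits from RGB-D images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated phenotyping of sectioned tomato fruits from RGB-D images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Internal fruit traits — locule number and area, mesocarp (pericarp wall)
thickness, stem-scar width and depth — drive tomato grading and breeding
decisions but are invisible from the outside. The standard workflow cuts
fruits longitudinally (through the stem-scar axis) or transversely (through
the equator), lays the sections on a white tray, and measures by hand with a
caliper. `tomatopheno` automates this: a top-view RGB-D camera supplies a
color image and a per-pixel distance map; segmentation isolates the fruit
and its internal structures; the camera's intrinsic parameters convert pixel
measurements into millimeters; and a depth-calibration model removes the
systematic bias that time-of-flight sensors exhibit on wet, specular plant
tissue. Twelve traits are reported per fruit: transverse and longitudinal
diameter, fruit shape index (longitudinal/transverse), stem-scar width and
depth, locule count, per-locule area, mesocarp thickness, and mean
mesocarp/locule colors.

# Pipeline components and their models

## Fruit isolation

Tray images contain several fruits on a bright background. Isolation works
in the HSV color space: fruit tissue is either saturated (red/orange/green
flesh) or dark, so the default foreground rule is `S >= 0.25 OR V <= 0.55`;
both thresholds are configuration entries. The raw mask is cleaned by
morphological closing and opening (5 x 5 elliptical kernel), then a Canny
edge map with filled external contours is unioned in to recover tissue lost
to the color rule (pale scar and placenta regions), followed by opening and
three erosions. Because erosion shrinks the silhouette and would bias every
diameter measured from it, the default configuration restores the extent
with an equal number of dilations; the restoration is switchable. Each
connected component above a minimum area becomes one fruit, cropped into a
fixed-size tile centered on its centroid (components too large for a tile
are downscaled and the factor recorded so predictions paste back exactly).
Fruit ids follow reading order of the centroids.

## Segmentation: a linear-attention hierarchical transformer

Stem scars and locules are segmented by a four-stage hierarchical
transformer encoder (downsampling 4/8/16/32) with an all-MLP decoder. The
attention inside every encoder block is a Mamba-like linear attention
(MLLA): queries and keys pass through an activation and a learned linear
map, then through the positive kernel `elu(x) + 1`, so attention weights
need no softmax and the output factors as

$$y_i = \frac{Q_i\left(\sum_j K_j^\top V_j\right)}{Q_i\left(\sum_j K_j^\top\right)},$$

computable in O(N) by accumulating the key-value summary once. The same sum
can be maintained as a running state (`S_i = S_{i-1} + K_i^T V_i`), which
the package implements as the `recurrent` evaluation mode; parallel,
recurrent and the O(N^2) double-sum reference agree to numerical precision
and are cross-checked in the test suite. Rotary position embeddings (RoPE)
on Q and K encode relative 2-D position (half of each head's feature pairs
rotate with the row index, half with the column index); a locally-enhanced
positional encoding (LePE) adds a 3 x 3 depthwise convolution branch to the
values. A linear projection maps each stage's tokens to the block embedding
before attention, and dropout (default 0.1) regularizes both residual
branches.

Two variants are provided: `a` with embedding dims (32, 64, 160, 256) and
depths (2, 2, 2, 2), `b` with (64, 128, 320, 512) and (3, 4, 6, 3), heads
(1, 2, 5, 8) so each head carries 32 channels. Tunables left open by the
architecture family were fixed once: feed-forward expansion ratio 3 and
decoder embedding 128, chosen so variant `a` lands in the ~3 M-parameter
class of lightweight segmentation backbones (it counts 2.79 M) and variant
`b` near 19 M; attention epsilon 1e-6; RoPE base 10000. The whole network —
forward pass and analytically derived backward pass — is implemented in base
R matrix code; a finite-difference directional derivative over all
parameters verifies the gradients to ~1e-9 relative error.

Training uses AdamW (base learning rate 1e-3, weight decay 0.01), batch
size 4, polynomial learning-rate decay `lr0 * (1 - t/T)^0.9`, and the
class-imbalance-aware hybrid loss `0.7 * CE + 0.3 * (1 - soft-Dice)`; stem
scars occupy only a few percent of pixels, which is what the Dice term
addresses. Dropout masks and batch order derive from one seed, so runs are
reproducible.

Because training a transformer in interpreted R is slow, the package's
tests train at desk scale: four 64 x 64 synthetic sections with three large
wedge locules each, where the lightweight variant reaches a foreground IoU
of 0.95 within a few hundred iterations (capped at 2000). This demonstrates
that the architecture, loss and optimizer are implemented correctly and can
fit sharp boundaries; it says nothing about generalization to real tomato
photographs, which would require the full-resolution training protocol on
real annotated data. For the classical measurement path the package also
provides a color-threshold segmenter, which is exact on flat-colored
synthetic sections and serves as the deterministic baseline in the
end-to-end tests.

## Depth calibration (HDRM)

Time-of-flight depth on sectioned fruit is biased: specular reflection off
the wet cut face, subsurface scattering and multipath effects produce
errors that grow with distance. The hybrid depth regression model corrects
a camera depth `d_c` in two stages:

1. **Parametric stage.** `d_param = (1 + alpha) d_c + beta d_c^2 + phi +
   gamma sqrt(d_c)`, fitted by linear least squares. A term linear in `d_c`
   for `gamma` would be collinear with the `(1 + alpha)` term and the
   normal equations would be rank-deficient; the square-root form keeps all
   four coefficients identifiable while still bending the curve at short
   range. A reciprocal form (`gamma / d_c`) is available by option.
2. **Residual forest.** The residual `e = d_b - d_param` is regressed on
   standardized extended features `[d, d^2, d^3, ln(d + 1), 1/d]` by a
   random forest (200 trees, seeded, ensemble mean); the final estimate is
   `d_final = d_param + e_hat`. Standardization statistics come from the
   training set only and are stored in the model.

Evaluation follows a 10-fold cross-validation: per fold both stages are
refitted and held-out RMSE is reported for the raw camera depth, the
parametric stage and the hybrid model. On simulations with a smooth
structured residual outside the parametric family, the hybrid model beats
the parametric stage, which beats raw depth, in at least 9 of 10 folds —
the qualitative ordering the method is designed to produce.

## Metric conversion and geometric primitives

With pinhole intrinsics `(fx, fy, cx, cy)`, a pixel `(u, v)` at depth `d`
back-projects to `((u - cx) d / fx, (v - cy) d / fy, d)`. Because a section
lies flat on the tray, all pixels of a fruit share one representative
depth, taken as the median of valid depth pixels inside the fruit mask
(robust to specular dropouts) and corrected by the HDRM when one is
supplied. Lengths convert by back-projecting both endpoints at that depth;
areas by the per-pixel footprint `(d/fx)(d/fy)`.

Three estimators operate on masks:

* `min_area_rect()` — exact rotating calipers: the minimal-area rectangle
  over a convex hull has a side collinear with a hull edge, so scoring all
  edge-aligned boxes is exact. The orientation is searched on the hull of
  pixel *centers* (the half-pixel corner dilation is anisotropic and would
  bias the chosen angle toward axis alignment), and the extents are then
  measured on the pixel *corners* at that orientation, so an axis-aligned
  filled `w x h` block measures exactly `w x h`.
* `oriented_extents()` — corner-span extents along the principal axes of
  the mask. For near-circular fruits the minimum-area criterion is
  degenerate under rasterization (a whole range of orientations ties within
  half-pixel noise, and the area landscape is flatter than that noise), so
  diameters are measured along the moment-based orientation, which is
  sub-pixel stable. Both estimators agree on elongated shapes.
* `rect_equivalent_extents()` — side lengths of the rectangle with the same
  second-order moments as the region (`side = sqrt(12 lambda + 1)`; the
  `+1` is the variance of a unit pixel footprint). Used for stem scars,
  which span only tens of pixels, where hull spans carry an O(1 px)
  rasterization bias but moments are unbiased.

Contours for ray casting (`mask_contour()`) are traced along boundary-pixel
centers, which sit systematically half a pixel inside the region footprint;
the polyline is therefore lightly smoothed (3-point moving average, which
removes the rasterization staircase) and offset outward by half a pixel
along the vertex normals. On analytic disks the first ray crossing then
lands within ~0.4 px of the true radius at any angle. For thickness this
offset is almost immaterial — both the locule and the outer contour shift
together and the gap between them is what is measured — but it makes
absolute distances to a single contour unbiased.

The longitudinal axis of a fruit cannot be inferred from side lengths
(tomatoes are typically oblate, longitudinal < transverse), so it is the
rectangle axis most parallel to the fruit-centroid-to-scar-centroid
direction; with an empty scar mask the fruit is assumed upright, the scar
fields are dropped and a warning raised.

## Trait extraction

Locule instances are connected components above 50 px (a speck filter for
segmentation noise), numbered by the polar angle of their centroid around
the fruit centroid, clockwise from 12 o'clock, so numbering is reproducible
across photographs of the same section. Mesocarp thickness is measured by
ray casting: per locule, a central ray from the fruit centroid through the
locule centroid plus two rays offset by +/-12 degrees; per ray, the
farthest crossing with the locule contour and the nearest outer-contour
crossing beyond it bound the flesh gap, and the ray thickness is the
minimum such gap. A ray that misses its locule is dropped; if all three
miss, the locule's thickness is reported as missing. Per-locule values are
the mean over surviving rays, the fruit value the mean over locules (rays
are averaged within locules first, so a dropped ray does not reweight the
other locules). Colors are sRGB channel means on the 0-255 scale: locule
color over each locule mask, mesocarp color over the pericarp band — the
flesh mask (fruit minus locules, minus the scar on longitudinal sections)
intersected with a 15 px erosion band at the fruit rim, inset 3 px from the
mask edge so mixed boundary pixels do not bias the mean. If the band is
empty it is widened once, then reported missing with a warning.

# The synthetic-section generator

Every stage is tested against rendered sections with analytically known
ground truth. A section spec defines an elliptical silhouette (semi-axes
`a`, `b` px, optional in-plane rotation), 2-10 wedge-shaped locules on an
annular ring (inner/outer radius, angular half-width, phase), a rectangular
stem-scar notch at the apex of the long axis (longitudinal sections), flat
8-bit tissue colors, and a constant true plane depth. The rendered camera
depth is the *inverse* of the parametric bias applied to the true depth,
plus Gaussian noise (default sd 2 mm, the magnitude of consumer
time-of-flight noise at ~0.6 m), rounded to integer millimeters — so a
correctly fitted HDRM recovers the true plane, making calibration a
well-posed recovery problem rather than a tautology. Ground truth
(diameters, scar size, locule areas as exact annular-sector areas, mesocarp
thickness as the analytic ellipse-radius-minus-ring-radius along each ray,
colors) is computed from the spec, never from the rendering.

Default conditions emulate a ~70 mm tomato at 600 mm under a 3600 px focal
length — the native scale of a 4K RGB-D capture, about 0.17 mm/px — so
structures like a 4-5 mm scar span ~28 px. Rendering uses hard pixel-center
color assignment rather than edge antialiasing: blended boundary pixels
would shift region-mean colors by several 8-bit units and break the color
oracle; an antialiasing option exists for robustness experiments (label
maps are always hard). What the generator does **not** emulate: texture and
color gradients inside tissues, irregular locule shapes (an option adds
boundary noise), specular highlights, depth dropouts, tilted sections
(a 5-degree tilt changes depth by a few millimeters across a fruit), or
annotation error. Passing the synthetic suite therefore validates the
geometry, calibration and bookkeeping of the pipeline — not photographic
robustness.

# Numerical choices and degenerate inputs

* Attention denominator guard 1e-6; the kernel is strictly positive, so the
  guard only matters for pathologically small activations.
* Linear least squares for the parametric depth stage (closed form,
  deterministic); rank deficiency raises an error naming the collinear
  terms.
* Forest, split, dropout and augmentation randomness all flow from explicit
  seeds (default 42); the train/val/test split (default 7:2:1, validation
  and test rounded, remainder to train) happens at tray-image level before
  augmentation so augmented copies of one image cannot leak across subsets.
* Empty masks: isolation returns an empty mask with a warning (not an
  error); an empty scar drops scar traits; zero locules yields an empty
  locule set. Depth 0 marks invalid pixels and is excluded from the median.
* Polygon rasterization uses the even-odd rule with boundary pixels
  included (closed fill), stated explicitly so annotation tests are
  deterministic.
* Test problem sizes — 512 px sections for measurement accuracy, 64 px
  four-image training for the overfit check, 264 calibration pairs with a
  9:1 split and 10-fold cross-validation — were chosen as the smallest
  sizes at which each property is meaningfully exercised.

# Known limitations

* The network trains at interactive speed only for small images; real
  deployments would train the same architecture in a compiled framework
  and import the weights.
* The planar-section assumption breaks for tilted fruits; no tilt
  correction is attempted.
* Color constancy across cameras is out of scope; colors are raw sRGB
  means under the capture illumination.
* The classical color segmenter requires tissue colors well separated from
  the background; it is a baseline and a fixture tool, not a substitute for
  the trained network on real images.
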