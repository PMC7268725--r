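---
title: "Counting maize kernels on ear images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting maize kernels on ear images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maizekern)
```

## The problem

The number of kernels per ear is a key yield indicator in maize breeding.
Counting kernels on a photograph of one side of an ear is hard for
classical segmentation because almost every kernel touches its neighbours,
the colour gradient across a contact is narrow, kernel shapes and sizes are
irregular, and illumination is uneven. `maizekern` implements a five-stage
recognition pipeline for 24-bit RGB photographs of a single ear against a
uniform blue (or dark) background, together with a synthetic ear-image
generator that provides exact ground truth, so that every stage is testable
without field photographs.

## The pipeline

`count_kernels()` chains five stages. All parameters live in
`pipeline_config()`; the defaults below are the pipeline's working set.

**1. Gaussian-pyramid compression.** Each pyramid step convolves with the
separable 5x5 binomial window (outer product of `c(1,4,6,4,1)/16`) and
keeps every second row and column, so level $i$ is

$$G_i(x,y) = \sum_{m=-2}^{2}\sum_{n=-2}^{2} w(m,n)\, G_{i-1}(2x+m,\, 2y+n).$$

The pyramid-generating window itself is a free choice (only its 5x5 support
is fixed); the binomial kernel is the canonical one and preserves constant
images exactly. Work happens at level 2 — a 16-fold pixel reduction
(compression ratio $100/4^i$ percent) that retains essentially all kernel
edges, whereas level 3 demonstrably loses them (`edge_integrity()`, a Canny
detector with hysteresis fixed at 80 and $80 \times 2.2 = 176$, counts far
fewer edge pixels at level 3 on generated ears). Restoration uses the dual
expand step with the same window scaled by 4.

**2. Background separation.** `mean_shift_filter()` performs joint
spatial–range mean-shift filtering: each pixel's window (spatial radius
`sp = 40` px at original scale, colour radius `sr = 60` intensity units)
iterates to its local mode and the pixel takes the converged window-mean
colour. This flattens within-kernel texture while keeping strong edges.
Two details are this package's own, because the procedure leaves them
open:

* the filter runs coarse-to-fine over up to `max_pyramid_level = 3`
  internal layers, with the spatial radius scaled by $2^{-\ell}$ per layer
  so the window always covers the same physical extent; and
* the expanded coarse result seeds a pixel only where it lies within `sr`
  of the pixel's own colour. An unconditional seed lets coarse-layer
  averaging pull fine-layer pixels into the wrong mode and erases the
  kernel structure wholesale; the guard keeps coarse-to-fine acceleration
  without that failure.

Since the filter runs on the compressed layer, `sp` is divided by the
compression factor (`scale_sp = TRUE`), keeping its physical meaning.

`segment_fruit()` then thresholds a single colour feature: against a blue
background the fruit is whatever has *low* blue intensity (the blue
histogram of a filtered ear image is strongly bimodal); against a dark
background, whatever has high `max(R,G,B)`. The cut defaults to the Otsu
(maximum between-class variance) threshold of that feature, computed by
exhaustive search over the 256-bin histogram. Holes are filled
(4-connected background not reaching the border) and 8-connected
components under `min_area = 20` px are removed. The same caller knows the
backdrop, so the mode is a configuration switch, not an inference.

**3. Edge enhancement by colour deconvolution.** The filtered image is
converted to an offset-128 Lab encoding,

$$L = 0.2126R + 0.7152G + 0.0722B,\quad
  a = 1.4749\,(0.2213R - 0.339G + 0.1177B) + 128,\quad
  b = 0.6245\,(0.1949R + 0.6057G - 0.8006B) + 128,$$

implemented in difference form so grey inputs map to $a=b=128$ bit-exactly.
Brightness and hue separate, and brightness is the feature that
distinguishes kernel crowns from the crevices between them. The Lab image
is then treated as if "stained" by a virtual dye: under the Lambert–Beer
model each channel's optical density $v' = -\ln((v+1)/256)$ is a linear
mix of per-stain densities, $v' = C^\top R^*$, so $R^* = (C^\top)^{-1} v'$
recovers the per-stain density map (`color_deconvolve()`). The shipped
library holds three single-vector stain combinations — methyl green,
hematoxylin GL, and an all-zero "white" vector that denotes a pure
brightness absorber and is completed to $(1,1,1)/\sqrt3$. A single vector
is completed to a full orthonormal matrix in the Ruifrok residual
convention (orthogonal swap vector, then the cross product), which makes
$C$ orthonormal and the inversion exact; the round trip
$256\exp(-C^\top R^*)-1$ reproduces the input to within quantisation.
`select_stain_combination()` picks the library entry whose stored Lab
centroid is nearest the fruit's mean Lab value; the shipped centroids are
the fruit means of the generator's three colourways and are a user-editable
config for real photographs. The first stain's display map is the working
grey image.

A note on what enhancement does and does not do here: with shadowed
crevices (the realistic case, and the case the rest of the pipeline needs),
the deconvolved display does not *amplify* the absolute crown-to-crevice
contrast relative to the L channel — the exponential display mapping is a
contraction. What it provides is a single scalar field in which the contact
lines stay well darker than the crowns (about 60 grey units on the
generated touching pairs) regardless of which of the three colour regimes
produced the image, which is exactly what the next stage requires.

**4. Local adaptive thresholding.** Every pixel is compared with the mean
grey of the `blocksize x blocksize` block centred on it (replicate
borders; integral-image implementation): strictly greater becomes
foreground. Ties go to background — a constant region therefore vanishes,
which is the strict reading of the rule and is pinned in a test. Because
the block mean shifts with any global offset, the output is *exactly*
invariant under uniform illumination change, and under gradients it beats
a global Otsu cut by construction. The block size is the average kernel
MBR length, estimated by `estimate_kernel_mbr()`: Otsu-binarise the grey
inside the fruit, label 8-connected components, drop those under 20 px and
the largest 5% (fused blobs), and average the axis-aligned bounding-box
sides. This bootstrap is an explicit engineering choice — kernel MBRs are
needed before kernels are segmented, so a rough first segmentation supplies
them; with fewer than three usable components a configured fallback (10x7
px at the working layer, the generator's kernel scale) is used with a
warning. The same small-area rule used on the fruit mask is applied once
more to the thresholded binary: speckle blobs below the noise floor would
otherwise survive smoothing as weak false peaks.

**5. Local-maxima recognition.** The binary is smoothed with an `N x N`
Gaussian (`N` = average MBR width rounded up to odd, $\sigma = N/6$ — the
usual three-sigma-in-window convention), which makes intensity grow toward
each kernel centre; an `L x L` block scan (`L` = `N`) accepts a pixel iff
no block member exceeds it and it strictly exceeds at least one. On
plateaus every member qualifies, so each 8-connected run of qualifying
pixels is reduced to the member nearest its centroid, making the result
scan-order independent. Finally points closer than `L/2` are single-linkage
clustered and each cluster collapses to its intensity-weighted centroid,
repeated to a fixed point, so output points are at least `L/2` apart and
the operation is idempotent. Points are reported at original-image
coordinates (times $2^{\text{level}}$). The pipeline contains no
randomness anywhere: identical input and configuration give identical
output.

Two baselines reproduce the classical failure modes: a gradient-vote
circular Hough transform (`hough_baseline()`) that misses or splits
low-roundness kernels, and iterative 3x3 erosion (`erosion_separation()`)
that separates corner-to-corner and edge-to-corner contacts but cannot
split an edge-to-edge pair before the kernels erode away, because the
contact chord there is longer than the kernel's minor thickness.

## The synthetic generator

`generate_ear()` renders an ear-like scene with exact ground truth:
a convex superellipse silhouette on a blue (40,60,205) or near-black
(18,18,18) backdrop, tiled with shaded elliptical kernels (nominally
40x28 px, 10% size jitter, per-kernel brightness jitter) in one of three
colourways (yellow dent, pale waxy, red flint). Choices that matter, all
made on realism grounds:

* **Shadowed crevices.** Kernel crowns blend into a dark rim colour and
  deep-gap colour. Brightness is the main crown/crevice separator; the
  crown-to-rim RGB distance exceeds the mean-shift colour radius, as it
  does in real photographs, so filtering preserves contact lines.
* **Kernels reach the silhouette.** The silhouette hugs and slightly clips
  the outer crowns — on a real ear the visible outline *is* the edge
  kernels. (A kernel-free flesh band around the grid would create
  boundary artefacts no real ear shows.)
* **Touching topologies.** Disjointly pre-matched neighbour pairs are
  pulled into contact: corner-to-corner (tangent diagonal or strongly
  offset vertical pairs), edge-to-corner (laterally offset vertical pairs,
  slight overlap), and edge-to-edge (horizontal pairs at centre distance
  0.68 of the summed half-widths, so the contact chord exceeds the kernel
  thickness — the configuration erosion provably cannot split). Where two
  kernels overlap deeply, a gap-coloured crease with a flat-topped profile
  marks the groove, wide enough to survive pyramid compression; real
  touching kernels always show such a groove.
* **Illumination is multiplicative** (reflectance times light field),
  normalised so the stated amplitude is realised on a nominally bright
  surface: a linear gradient of amplitude 60 spans at least 55 units
  across the ear while a black cloth backdrop stays dark, as in a real
  scene. An additive field would brighten the backdrop itself and change
  the segmentation problem.
* Per-pixel Gaussian noise (sd 3) and optional bald tip and highlight
  fields complete the scene.

What the generator does **not** emulate: perspective foreshortening and
the resulting occlusion of kernels on the ear's silhouette edge, specular
highlights with clipping, camera noise correlation, cob colour showing
between sparse kernels, and natural row curvature. Passing tests on these
fixtures therefore validate the pipeline's mechanics (stage contracts,
separation of the three contact topologies, illumination robustness), not
field accuracy on photographs; the published per-variety accuracies are
not reproducible without the original images.

The standard validation suite (`standard_suite()`) fixes 50 specs, seeds
1–50: 5–8 rows by 4–6 columns (20–48 kernels), touching fraction up to
30% split evenly over the three topologies, gradient illumination of 60
units, alternating blue and black backgrounds. Fixture images are roughly
360x230 px, processed at pyramid level 2 (about 90x60); the whole suite
runs in a few seconds.

## Evaluation metrics

`evaluate_detections()` matches detections to true centres greedily by
ascending distance, one-to-one, with matches beyond `match_radius`
(default half the nominal kernel width — a point inside a kernel's core)
rejected. Correct = matched detections; false positives = unmatched
detections; false negatives = unmatched truths; correct rate =
100 x correct / truth, to one decimal. Greedy matching coincides with
optimal assignment when the radius is small against kernel spacing, which
it is here. Published tables are ambiguous between truncation and half-up
rounding of the rate (they contain one row consistent only with each);
both conventions are exposed (`rounding=`), with half-up the default.
Batch averages are the arithmetic mean of per-image rates, not the pooled
rate.

## Numerical and degenerate-input choices

* Pyramid: replicate-edge padding everywhere (avoids dark halos that would
  bias later thresholds); odd dimensions ceil-halve, and `pyr_up()` takes
  an explicit `out_dim` for round trips.
* Otsu: exhaustive search over all 256 bins, first maximum on ties;
  single-bin histograms yield an empty mask with a warning.
* Adaptive threshold tie rule: `c = M` is background.
* Mean shift: `max_iters = 5`, `eps = 1` by default (speed); the filter is
  idempotent on mode-structured scenes, but on continuous shading ramps a
  second pass keeps drifting — a property of mode seeking with a mean
  rewrite, documented rather than hidden.
* Plateau maxima: member nearest the plateau centroid, then `L/2`
  single-linkage merging to the intensity-weighted centroid, iterated to a
  fixed point.
* Empty fruit mask short-circuits to a zero count; stage errors propagate
  with the stage name attached.
* Hough baseline acceptance threshold: a fixed rule
  (`max(6, 0.9*pi*r_min)` votes) recorded in the signature, radii bounds
  defaulting to 0.3–0.7 of the average MBR width.

## Known limitations

Occluded kernels on the silhouette edge are not recognised (one-sided
imaging); bald-tip areas that survive the colour threshold can contribute
false positives (no shape-based bald-tip classifier is attempted); the
stain library is fixed rather than estimated from the image; and accuracy
figures on synthetic fixtures are an upper bound on what real photographs
would give.
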