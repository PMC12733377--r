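---
title: "Methods: semi-automated annotation transfer from H&E to fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automated annotation transfer from H&E to fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(annotransfer)
```

## The problem

Deep-learning models for fluorescence microscopy of unprocessed tissue — for
example MUSE, microscopy with ultraviolet surface excitation — need tumor
labels on the fluorescence images themselves, but pathologists annotate the
H&E sections that are produced later from the same block. Between the two
acquisitions the tissue passes through formalin fixation and paraffin
embedding, which stretches, shrinks, tears and sometimes loses material, and
the sectioning depth differs from the imaged surface. A rigid or affine
alignment cannot absorb these local deformations, and the two modalities
differ too much in contrast and resolution for reliable automatic intensity
matching. This package implements a semi-automated transfer built around
hand-picked landmark pairs, which remains the robust choice in this regime.

## The registration model

A pair of degree-2 polynomials maps a raw fluorescence pixel $(x, y)$ into
the H&E frame:

$$X = a_0 + a_1 x + a_2 y + a_3 x^2 + a_4 x y + a_5 y^2,$$
$$Y = b_0 + b_1 x + b_2 y + b_3 x^2 + b_4 x y + b_5 y^2.$$

Twelve coefficients allow smooth local nonlinearity — quadratic bending on
top of an affine core — while remaining fit-able from as few as six landmark
pairs, the minimum for which the per-axis linear system is determined.
`fit_transform()` solves each axis by least squares on the design matrix
$[1, x, y, x^2, xy, y^2]$ using a pivoted QR decomposition; normal
equations would square an already delicate condition number.

Three numerical choices matter:

* **Coordinate normalization.** Raw pixel coordinates at slide scale
  ($10^3$–$10^4$ px) make the quadratic columns dwarf the constant column
  and the fit ill-conditioned. Coordinates are therefore divided by image
  width (x) and height (y) before fitting — the `"wh"` convention, with
  `"max"` (divide both by the larger dimension) available as an
  alternative, since published coefficient sets do not always state their
  convention. The transform object records the convention and both image
  shapes, so pixel in / pixel out behavior is unambiguous.
* **Condition cap.** A landmark set that is collinear or tightly clustered
  leaves the quadratic surface nearly unconstrained; the resulting
  extrapolation is wild but silent. Fits whose design-matrix condition
  number exceeds `condition_cap` (default $10^8$) are hard errors.
* **Inverse mapping.** A degree-2 polynomial has no closed-form inverse.
  Warping uses the output-to-input convention (each output pixel samples
  the input image), and the "inverse registration" that carries the refined
  annotation back to raw fluorescence space is a separately fitted
  transform with the fixed/moving roles swapped. For the mild warps this
  pipeline targets (quadratic coefficients up to about 0.1 in normalized
  units) the two fits compose to identity within half a pixel at a
  1000-pixel scale, which the test suite asserts.

Interpolation is bilinear for images and nearest-neighbor for masks — the
only choice that keeps a mask binary. Out-of-frame samples take the
background value 0; both modalities are dark outside the tissue.

## Annotation extraction and refinement

The pathologist's outline is recovered by subtracting the clean H&E export
from the annotated one and flagging pixels whose maximum per-channel
absolute difference exceeds `diff_threshold` (default 10/255 — JPEG-encoded
exports differ slightly everywhere, so an exact-zero test would flag the
whole image). Subtraction is color-agnostic; no stroke color is assumed.
Because hand-drawn outlines are rarely closed at export resolution, the
outline is morphologically closed with a disc (radius 5 by default, a few
stroke widths) and then filled: interior holes become foreground, anything
connected to the border background stays background, and multiple disjoint
outlines are all filled. Foreground is treated as 8-connected and
background as 4-connected, avoiding the fill/boundary topology paradoxes.

The drawn region may legitimately overhang the tissue into background —
pathologists include regions that could hold tumor in deeper sections — but
a surface fluorescence image has no such content. The **tissue mask**
removes it: on the grayscale registered fluorescence image, Canny edges are
detected (fluorescence tissue is densely textured, so edges fire throughout
its interior), gaps are closed with a disc structuring element of size 55,
holes are filled, the binary mask is smoothed as a real-valued image with a
Gaussian of size 63 and $\sigma = 53$, and pixels strictly above 0.1 are
kept. The element and window sizes are interpreted as widths, the common
structuring-element convention. The printed $\sigma$ far exceeds the
window, so the kernel is explicitly truncated to the 63-pixel window and
renormalized, giving near-box smoothing; both printed numbers are honored
as stated rather than reinterpreted. Hole filling is placed between closing
and smoothing because a solid tissue region cannot arise from edges plus
closing alone; the chosen order is covered by the phantom tests. Canny
thresholds default to the 70th/90th percentiles of the nonzero gradient
magnitudes, which also makes the mask invariant to uniform intensity
scaling; explicit thresholds can be configured.

One scale effect is worth knowing: smoothing a mask with a fixed 63-pixel
near-box kernel and keeping everything above 0.1 moves the mask boundary
outward by roughly 25 px regardless of image size. On slide-scale images
this is negligible; on desk-scale test images it is visible, which is why
the package's phantom defaults use a 768-pixel frame with tissue filling
most of it.

The **refined annotation** is the intersection of the annotation mask with
the tissue mask after eroding the latter with a disc of size 15 (the
published chain states the erosion but not its size; it exists to trim
segmentation boundary artifacts, and 15 px removes the typical halo without
eating into tissue). The refined mask is then inverse-registered into raw
fluorescence space with nearest-neighbor sampling and its boundary — the
mask minus its one-pixel erosion — is drawn onto the raw image.

## Agreement metrics

* **Dice coefficient**, $2|I_1 \cap I_2| / (|I_1| + |I_2|)$, computed on
  filled region masks. Two empty masks score 1, one empty mask scores 0;
  reports flag the degenerate case.
* **Normalized Hausdorff distance**: the symmetric Hausdorff distance
  between the two boundaries in Euclidean pixels, divided by the maximum
  image dimension so differently sized samples are comparable. The
  symmetric (undirected) form is the default; directed variants are
  available behind a flag.
* **Feature similarity**: cosine similarity of feature vectors from a
  pluggable extractor. The default is a deterministic handcrafted
  descriptor (multiscale block-mean intensities plus gradient-orientation
  histograms), which keeps the entire test path offline; an adapter for a
  pretrained convolutional network (the published scores used an AlexNet
  fully-connected layer) satisfies the same contract — any deterministic
  function from an image to a fixed-length vector — when approximating
  published similarity values matters. Which network layer and what
  preprocessing produced those values is not stated, so the contract
  deliberately leaves both to the plugin.

Batch summaries report minimum, quartiles, median, maximum and
$1.5 \times \mathrm{IQR}$ outliers per metric. Quantiles use linear
interpolation between order statistics (R type 7), stated here so tabulated
summaries are exactly reproducible.

## The phantom generator

`generate_phantom()` builds a paired sample with complete ground truth: a
smooth star-shaped tissue blob (radius modulated by a low-order Fourier
series) with speckled nuclear texture, rendered in an H&E-like palette for
the fixed frame and a fluorescence-like palette (dark background, green
cytoplasm, bright red nuclei) for the moving frame; a tumor subregion whose
outline is drawn on the annotated copy (the ground-truth tumor mask is the
region the stroke encloses, stroke included); a known degree-2 warp; and
landmark pairs placed on the tissue boundary, where human pickers find the
strongest cross-modality features. Moving landmarks are obtained by Newton
inversion of the true warp, so they satisfy it to machine precision and a
fit on them must recover the generating coefficients — an end-to-end
exactness check the suite runs over many seeds.

Default conditions, chosen once as a desk-scale stand-in for slide data: a
768 px frame; tissue radius 0.40 of the frame (so the fixed smoothing halo
stays small relative to the tissue); tumor radius 0.45 of the tissue
radius, placed anywhere inside the tissue including near its margin (margin
involvement is the clinical point); twelve landmarks; quadratic warp
magnitude 0.05 in normalized units with the constant terms re-centered so
the tissue center maps to the frame center, as an operator framing the
sample would; additive Gaussian intensity noise of 0.01; stroke width 3 px.
Landmark error is modeled by `perturb_control_points()` (Gaussian
displacement of the moving points only). Tissue loss is modeled on the
paper's described failure mode: bites are torn from the tissue margin
(interior holes would simply be re-filled by the hole-filling step), and
any moving landmark inside a bite snaps to the bite rim — the boundary a
human picker would actually see — so severe loss corrupts the registration
itself.

What the phantoms do not emulate: real stain variability, resolution and
magnification differences between modalities, focal blur, stitching seams,
folding, and genuinely textured (non-speckle) histology. Passing phantom
tests therefore demonstrates the correctness and stability of the
algorithms under known deformations, not clinical-grade performance on real
slides, which the published evaluation addresses with real sample pairs.

## Problem sizes used by the test suite

End-to-end checks run the full pipeline on 768-pixel phantoms over 20 seeds
(exact landmarks) and 10 seeds per jitter level $\sigma \in \{2, 5, 10\}$
px; unit and property tests use 256–384 px phantoms and 16–32 px toy masks
against exhaustive brute-force oracles. These sizes keep the complete suite
within a few minutes on a single CPU while staying large relative to every
structuring element in the chain.

## Known limitations

* The published coefficient example cannot be reproduced beyond its printed
  constant terms because the original coordinate-normalization convention
  is unstated; the package makes the convention explicit and configurable
  instead of guessing.
* The interactive landmark-refinement loop (pick points, watch the tissue
  Dice, adjust) is intentionally not automated; the package computes the
  quality score (`registration_quality()`) but point selection stays human.
* Published deep-feature similarity values depend on specific pretrained
  weights that are not bundled; the built-in descriptor is a contract
  stand-in, not an approximation of those values.
* Masks written to PNG are strictly binary `{0, 255}`; gray masks from
  foreign tools are rejected rather than silently thresholded.
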