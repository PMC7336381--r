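---
title: "Filament picking by oriented line enhancement, ridge detection and directional tracing"
author: "filatrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filament picking by oriented line enhancement, ridge detection and directional tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filatrace)
```

## The problem

Helical protein assemblies — F-actin, microtubules, tobacco mosaic
virus, amyloid fibrils — appear in cryo-EM micrographs as dark,
line-like structures at a very low signal-to-noise ratio. Helical
reconstruction needs thousands of square boxes placed along each
filament, while crossings, near-parallel close pairs, broken stretches
and carbon-film edges must be excluded because their overlapping density
corrupts downstream 2-D class averages. This package implements two
complementary picking routes plus the machinery to evaluate them:

* a **classical route**: enhance lines with a bank of oriented
  second-derivative Gaussian kernels, detect ridges with a Steger-style
  subpixel line detector, split at crossings, filter, and place boxes;
* a **tracing route** for candidate boxes from any upstream detector
  (e.g. a CNN picker): order the unlabeled boxes into filaments using
  the directional map of the same oriented filter bank, then resample
  at a fixed spacing.

## The oriented filter model

A line of width $f_w$ oriented at $\theta$ is enhanced by the second
derivative (taken across the ridge) of an anisotropic Gaussian
$$M(x,y) \;=\; \partial_a^2\!\left[
\frac{1}{2\pi\sigma_x\sigma_y}
e^{-a^2/2\sigma_x^2}\,e^{-l^2/2\sigma_y^2}\right],$$
where $a$ and $l$ are the across- and along-ridge coordinates after
rotation by $\theta$. The spreads derive from full widths at half
maximum: $\sigma_x = f_w / (2\sqrt{2\ln 2})$ controls the line width the
kernel responds to, and $\sigma_y = m_w / (2\sqrt{2\ln 2})$ sets how far
the kernel averages along the line. Discrete kernels are mean-subtracted
to an exactly zero sum, which makes every response invariant to additive
intensity offsets.

The per-pixel maximum response over a bank of rotated kernels is the
enhanced image $U$; the angle attaining the maximum is the directional
map $V$. The ridge detector runs on $U$; the box tracer reads directions
from $V$.

Parameters that matter, with defaults:

| parameter | default | unit | role |
|---|---|---|---|
| `fw` | — | px (working image) | filament width (FWHM); sets $\sigma_x$ and the ridge-detection scale |
| `mw` | 100 | px | along-ridge averaging (FWHM); lower it for flexible filaments |
| `nAngles` | 36 | — | bank orientations over $[0,\pi)$, i.e. a 5° step |
| `upper`, `lower` | — | — | hysteresis thresholds on the normalized ridge strength |
| `binFactor` | 4 | — | block-average binning before everything else |
| `lowpassCutoff` | 0.1 | cycles/px | Gaussian low-pass on the binned image |
| `clipSigma` | 3 | sd | saturation after z-normalization |
| `minLength` | 0 | px (unbinned) | minimum filament arc length |
| `boxDistance` | 20 | px (unbinned) | output box spacing |

The mask width deserves emphasis: $m_w = 100$ px suits nearly straight
filaments. The synthetic scenes used throughout the tests have bounded
curvature $0.002\,\mathrm{px}^{-1}$ (minimum bend radius 500 unbinned
px, 125 binned px); averaging over $\pm 3\sigma_y \approx \pm 127$ px
along a straight line then destroys the ridge contrast of curved
filaments, so the test studies run with $m_w = 20$. This mirrors actual
practice: the mask width is reduced for flexible specimens.

Angular sampling uses 36 angles (5°); the directional map's worst-case
error on a straight filament is then half a step, 2.5°. Kernel support
is truncated at $3\sigma$ on each side (rounded up to odd) and clamped
to the working image when $m_w$'s extent exceeds it; the clamp cuts the
Gaussian at $\geq 2.9\sigma$ for every configuration the tests use,
which is numerically immaterial.

## Ridge detection

Detection follows the classical differential-geometric recipe at scale
$\sigma = f_w/(2\sqrt{2\ln 2})$:

1. Gaussian-derivative filtering yields the smoothed partials $r_x,
   r_y, r_{xx}, r_{xy}, r_{yy}$.
2. Per pixel, the eigenvector of the Hessian with the most negative
   eigenvalue $\lambda$ gives the ridge normal $(n_x, n_y)$; the
   subpixel extremum along the normal is $t = -(r_x n_x + r_y
   n_y)/\lambda$, and the pixel is a line point when $|t\,n_x|,
   |t\,n_y| \le 1/2$. The strength $s$ is $|\lambda|$ normalized per
   image to $[0,1]$ (the strongest line point defines 1); this is the
   quantity the hysteresis thresholds act on, so thresholds are
   transferable between images of similar content.
3. Linking generalizes hysteresis thresholding: points with $s <$
   `lower` are dropped (plus a floor of $0.01$ below which saliency is
   numerical noise), lines are seeded at the strongest unvisited point
   with $s \ge$ `upper` and extended in both directions through the
   8-neighbor of highest $s$ whose normal differs by less than 45°,
   with a no-backtracking constraint on the step direction. When an
   extension selects a point of another line, that point becomes a
   junction and the touched line is split there; the junction pixel
   stays with one half only, so every point belongs to at most one
   line. Two robustness rules matter on noisy enhanced images: a
   single-point seed colliding immediately with an existing line is a
   spur, not a junction; and when no compatible continuation exists but
   a neighbor belongs to another line, the collision still counts as a
   junction, because normals are unreliable exactly at crossings.
4. Width estimation walks the gradient magnitude along both senses of
   the normal (1 px steps, parabolic peak refinement) to the left and
   right edge maxima. The reported width deconvolves the detection
   scale from the edge distance assuming a Gaussian cross profile
   (`widthRaw` keeps the raw distance, which is biased wide by about
   the detection scale).
5. Position refinement moves each point along its normal toward the
   narrower flank by half the edge-distance imbalance, clamped to 1 px:
   smoothing biases a ridge with unequal flanks toward the broader
   side, and the edge imbalance is a direct estimate of that bias.
   Symmetric profiles are left in place.

## From lines to filaments

The pipeline trims line ends near *transversal* junctions — those where
another line passes at more than 30° — by $f_w/2$ plus a 2 px
junction-localization margin, so no box lands within half a filament
width of a crossing. Collinear collisions (noise stubs that rejoin their
own ridge) are deliberately not trimmed. Afterwards, collinear pieces
whose free ends face each other across a gap of at most $3 f_w$ are
merged (both end tangents within 25° of the connecting line, tangents
measured over an 8-point baseline to be robust to subpixel refinement
jitter); ends created by a crossing trim never merge, so crossings stay
skipped. Coordinates are mapped back to unbinned pixels and filaments
shorter than `minLength` are dropped. Optional binary masks (nonzero =
valid) remove points over carbon or contamination; filaments are
re-split and re-filtered at the removed runs. Boxes are finally placed
by arc length at 0, $d$, $2d,\dots$, giving $\lfloor L/d \rfloor + 1$
boxes per filament.

## Threshold optimization

The hysteresis thresholds are hard to guess, so they are fitted to one
to three manually annotated micrographs. Phase 1 fixes `lower` $=0$ and
scans `upper` for pixel-level recall of the annotation. Recall is
nearly flat over a plateau of `upper` values, and the plateau's edges
are both treacherous: at its low end part of the recall is contributed
by noise lines that happen to graze the annotation (precision
collapses), while very large values start missing detections on images
whose contrast differs from the training draw. Phase 1 therefore keeps,
among the thresholds whose recall lies within 0.02 of the maximum, the
smallest one whose precision is within 0.05 of the best in that set —
the least selective setting that already separates detection from
noise. Phase 2 raises `lower` in 0.01
steps for as long as recall stays within 0.02 of its phase-1 value,
which removes weak false-positive lines at no recall cost. The `upper`
scan is coarse-to-fine (0.05 grid, then 0.01 refinement around the
coarse optimum): recall varies smoothly with `upper`, and the
refinement reaches the same 0.01 resolution as an exhaustive grid at a
quarter of the cost. An explicit `upperGrid` argument restores the
exhaustive scan.

Because the strength $s$ is normalized per image by its maximum, any
dominant high-contrast line — a carbon edge above all — rescales every
filament's strength downward. Thresholds must therefore be fitted on
micrographs representative of the data they will be applied to,
including such artifacts; the carbon-edge studies in the test suite fit
their thresholds on annotated carbon-containing scenes for exactly this
reason, and that is also how the annotate-then-optimize workflow plays
out on real data sets.

## Tracing candidate boxes

Candidate boxes arrive unordered. Tracing picks a random untraced box
(seeded RNG, so runs are reproducible), reads the filament orientation
from $V$ at the box center, and repeatedly appends the nearest untraced
box within a radius of 1.5 box sizes and within a cone of $\pm 60°$
($\alpha = 120°$) around the current direction — both senses for the
first step, since a single box only knows its orientation, forward-only
afterwards. When growth stops, the trace continues from the seed in the
opposite sense. A search that reaches a box of another filament merges
the two segments when their end directions differ by at most 30°
(measured modulo $\pi$), so perpendicular filaments never merge.
Filaments with fewer than 2 member boxes are discarded before
resampling, which re-places boxes along the fitted polyline at the
user's spacing, exactly as in the classical route.

## Evaluation metric

Predicted and reference filaments are compared at pixel level. Both
sets are rasterized by stamping all pixels within $f_w/3$ (rounded) of
the centerline; the difference $D = B_u - B_p$ is split into its
positive part $D_1$ (missed) and negative part $D_{-1}$ (spurious);
both parts are morphologically opened and counted:
$\mathrm{FN} = |D_1 \circ M|$, $\mathrm{FP} = |D_{-1} \circ M|$,
$\mathrm{TP} = |B_u| - \mathrm{FN}$, with precision
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FP})$ and recall
$\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$.

The opening element $M$ is a disc matched to the tube radius
$\mathrm{round}(f_w/3)$. This choice is load-bearing: the rasterized
tube is by construction the dilation of its centerline by exactly this
disc, so the opening reproduces a fully missing filament verbatim (an
empty prediction scores recall exactly 0) while deleting jitter slivers
narrower than the tube in any orientation. A square element of side
$f_w$ would be wider than the tube itself and would erase whole missing
filaments from $D_1$ — recall would then saturate at 1 no matter what —
and a square additionally acts anisotropically on diagonal tubes.

Pixels within $f_w$ of the image border or of any filament endpoint are
excluded from the counts (not blanked from the images, which would
break the opening's exactness at the cut edges): start and end points
of manual traces carry high uncertainty. A metric whose denominator is
zero is reported as undefined with an explicit flag, never silently 0.
Because TP counts truth pixels, swapping truth and prediction swaps FN
with FP exactly but precision with recall only approximately.

## The synthetic scene generator

Tests and the acceptance script run on generated micrographs with known
ground truth. Centerlines are random walks of the heading with bounded
curvature (default $0.002\,\mathrm{px}^{-1}$), 300–900 px long, rendered
as dark ridges with a Gaussian cross profile of FWHM `fw` (default
24 px, roughly a 200 Å filament at 4 Å/px after no binning). Requested
features are inserted explicitly: filaments forced to cross an earlier
one at 40–140°, near-parallel copies at a configurable centerline gap,
unrendered gap intervals (discontinuities), and a dark half-plane with a
sharp vertical edge emulating the carbon film (filament placement then
avoids the carbon side, so masking experiments isolate the edge's
false positives). White Gaussian noise of unit standard deviation is
added last; the contrast-to-noise ratio `snr` is defined as peak
centerline depth over noise standard deviation (default 0.5 — the
per-pixel signal sits well below the noise, and detection is only
possible because the oriented kernel averages along the ridge).
Everything is deterministic given the seed.

What the generator does *not* emulate: CTF oscillations, structured ice
and ethane contamination, radiation-damage gradients, the helical
repeat texture of real filaments, and realistic carbon textures.
Passing the synthetic studies therefore demonstrates the geometry and
statistics of the method — not its performance on any particular
microscope's data, for which the threshold optimizer exists.

## Problem sizes used by the test-suite studies

The end-to-end studies evaluate 20 held-out scenes of 1024² px (binned
to 256² for detection) with thresholds fitted by the optimizer on two
annotated training scenes, plus 3 carbon-edge scene pairs; the
acceptance script repeats the same computation with 8 evaluation
scenes. Smaller unit fixtures (64²–512²) exercise each stage in
isolation.

## Numerical choices and degenerate inputs

* Convolution runs in the frequency domain after reflect padding by the
  kernel half-size; kernels are point-symmetric, so correlation and
  convolution coincide.
* Argmax ties across bank angles resolve toward the smallest angle.
* A subpixel extremum landing exactly on a pixel boundary is accepted
  on both sides (tolerance $10^{-9}$); the linking's visited-once rule
  keeps the duplicate out of a second line.
* Constant images: zero-variance input is an error in preprocessing;
  a flat image yields an all-zero strength field and no lines.
* Edge search failures (border, no maximum inside the range) flag the
  width as missing rather than guessing.
* The EMAN helical dialect writes 0-based lower-corner coordinates with
  -1/0/-2 segment flags; the STAR dialect writes 0-based centers with a
  configurable helical-tube id column; package-internal coordinates are
  1-based pixel centers (x = column, y = row), the native R convention.

## Known limitations

* The strength normalization is per image, so hysteresis thresholds
  transfer between images only when content is comparable — hence the
  optimizer.
* Junction localization degrades when more than two filaments meet in
  one spot; trimming still isolates the region but may cut more than
  $f_w/2$.
* The tracer is greedy; with very dense candidate sets an unlucky seed
  order can split one filament in two at a sharp bend (the merge rule
  usually, but not provably, repairs this).
* Width estimates assume an approximately Gaussian cross profile;
  hollow or double-walled filaments (e.g. microtubules seen side-on)
  will read wide.
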