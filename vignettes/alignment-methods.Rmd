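---
title: "Aligning paired forearm POCUS views: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning paired forearm POCUS views: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocusalign)
```

## The problem

A longitudinal wrist ultrasound shows one echogenic cortex of the radius:
the dorsal scan shows the dorsal cortex, the palmar scan the palmar one.
Neither alone shows fracture angulation. If the two views are brought into a
common frame — palmar view mirrored, then rigidly moved so that the physes
correspond and the two shaft boundaries run parallel at one bone width —
the pair reads like a lateral radiograph. `pocusalign` automates that
alignment from segmented bone-boundary masks. Segmentation itself is out of
scope: any upstream method that yields a binary boundary raster (deep
segmentation, manual tracing) can feed the pipeline.

## Coordinate conventions

All computations run in physical millimetres in the image frame: origin at
the centre of the top-left pixel, x rightward, y **downward**, pixel indices
times the isotropic spacing. Rotations are parameterized so that positive
`theta` turns `(1, 0)` towards `(0, 1)`. The mirror used for
opposite-orientation views is `x -> -x` about `x = 0`, applied *before* the
rigid part; a `rigid_transform` therefore has an orthonormal linear part with
determinant +1, or -1 when `pre_flip` is set. Angles are radians internally,
degrees at all I/O boundaries.

The transform is restricted to mirror + rotation + translation rather than a
general 3x3 affine. All three alignment constraints are satisfiable rigidly,
and admitting scale would let the energy collapse the moving view; the
orientation constraint's fixed normalization would otherwise act as an
implicit and poorly controlled scale regularizer.

## Landmark extraction

A boundary mask is reduced to an ordered centerline polyline: largest
8-connected component, Zhang-Suen thinning, pruning of skeleton spurs
shorter than 2 mm, a two-endpoint topology check (more endpoints after
pruning is an error, not a guess), and breadth-first path ordering from the
leftmost endpoint.

Three landmarks are then placed:

* `L_d1` — windows of `min_diaphysis_length` (default 15 mm) slide along the
  curve; a window is diaphysis-like when its least-squares direction is
  within `horizontal_tol` (default 20 degrees) of horizontal. Within the
  longest such run, `L_d1` sits at the 90th percentile of x. The percentile
  placement has two purposes: it stays clear of the metaphyseal flare at the
  run's end, and it makes the position insensitive to where exactly the run
  begins (a shift of the run start moves the 90th percentile by only a tenth
  of that shift).
* `L_d0` — 25 mm back along the curve from `L_d1` (arc distance, not chord;
  configurable within the clinically stated 2-3 cm).
* `L_p` — the physis: the point maximizing `y - 0.2 x` within the leftmost
  35 % of the curve's x-range, i.e. the lower-left extremity with ties
  broken towards "lower". The weight 0.2 and the 35 % window are engineering
  choices for a region that clinical practice describes only qualitatively.

Views acquired from the opposite orientation have the physis on the right;
`physis_side = "right"` mirrors the curve internally and mirrors the result
back, so the two conventions are exactly symmetric. `run_align` selects this
automatically for the moving view when `pre_flip = TRUE`.

All tie-breaks take the first occurrence in traversal order; identical mask
and configuration give bit-identical landmarks.

## The alignment energy

With fixed landmarks `L^f` and moving landmarks `L^m`, the energy is

$$E = w_a C_a + w_o C_o + w_p C_p$$

* `C_a` (physis): `w_x |L^f_{p,x} - T(L^m_p)_x| + w_y |d - L^f_{p,y} + T(L^m_p)_y|`.
  Zero when the transformed moving physis sits directly at the fixed physis
  x-position, offset by `d` vertically.
* `C_o` (parallel shafts): distance between the two unit diaphysis
  directions, the moving one rotated by the transform's linear part and
  normalized by its untransformed length. Ranges over [0, 2].
* `C_p` (bone width): `| |(T(L^m_mid) - L^f_{d0}) . n^f| - w |`, the
  unsigned point-to-line distance of the transformed moving shaft midpoint
  from the fixed shaft line, minus the target width `w`. The subtraction of
  `w` implements the anatomical statement that the two cortices sit one bone
  width apart; at `w = 0` the term reduces to the bare point-to-line
  distance, which on its own admits the degenerate solution of both shafts
  collapsing onto one line.

### Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `w_x`, `w_y` | 1, 1 | — | x/y weighting inside `C_a` |
| `w_a`, `w_o`, `w_p` | 1, 1, 1 | — | outer constraint weights |
| `d` | 10 | mm | target vertical physis offset |
| `w` | `d` | mm | target bone width |
| `learning_rate` | 0.05 | — | gradient-descent step |
| `iterations` | 10000 | — | fixed descent budget, no early stopping |
| `fd_step` | 1e-4 | optimizer units | central-difference step |

`C_o` is dimensionless while `C_a` and `C_p` are in mm; with unit weights a
1 mm positional error and a full unit-vector mismatch count comparably. The
weights are exposed for retuning rather than rescaled internally. No
published values exist for `d` and `w`; 10 mm approximates a pediatric
distal radius width, and using `d = w` reflects that the physis offset in
the fused view is the same cortex-to-cortex distance. Whenever the phantom
generator is the data source, `d = w = bone_width` makes the ground-truth
configuration an exact zero of the energy.

## Optimization

The energy is a weighted sum of absolute values — piecewise smooth with
kinks exactly at the constraint zeros. Three numerical choices follow from
that structure:

* **Central finite differences** (step `1e-4`) handle the kinks uniformly:
  at a symmetric minimum the symmetric difference evaluates to zero, so an
  already-optimal start is a fixed point of the iteration.
* **Preconditioned parameterization.** Gradient descent with one fixed
  learning rate needs comparable curvature in all coordinates. Rotation is
  therefore taken about the moving physis and the angle coordinate is scaled
  by the mean distance of the diaphysis landmarks from that centre (~40 mm),
  so a unit step in the angle coordinate moves landmark positions by about a
  unit in mm, like the translation coordinates. Without this, the angle
  coordinate oscillates with amplitude proportional to the landmark radius
  and the descent cannot settle. The finite-difference step is applied in
  these internal coordinates; the returned transform is converted to the
  canonical about-the-origin form.
* **Closed-form initialization (default `init = "diaphysis"`).** The
  rotation is directly observable as the angle between the two diaphysis
  directions, and the translation as the offset that places the moving
  physis at its target; the descent then refines the joint optimum of all
  three coupled constraints. A physis-translation-only start (`init =
  "physis"`) is retained but not default: from `theta = 0` the descent first
  drives the strongly-sloped mm-scale terms to zero and then has to crawl
  along their zero manifold driven only by the weak orientation term, whose
  effective gradient in the preconditioned angle coordinate is ~1/40 — a
  fixed-budget descent can stall tens of degrees short. The closed-form
  start removes that failure mode without touching the energy or the descent
  itself.
* **Best-iterate return.** With a constant learning rate on a kinked
  energy the final iterates oscillate in a band around the minimum; as is
  standard for subgradient methods the iterate with the lowest energy seen
  is returned (and appended as the trace's final row), which also guarantees
  the returned energy never exceeds the initial one. The trace records the
  raw path.

The discrete mirror cannot be descended upon, so `pre_flip` is fixed before
optimization; opposite-orientation acquisition is known at scan time, so
this is an input, not an estimate.

Degenerate inputs fail loudly: zero-length diaphysis segments, non-finite
energies (with the iteration number), empty masks, skeletons with ambiguous
topology.

## Fusion and angulation

The fused view resamples the moving image onto the union bounding box of
both extents (5 mm margin) by inverse-mapped bilinear interpolation
(nearest-neighbour for masks), keeping the two channels separate — rendered
red (fixed) and green (moving) — rather than compositing intensities, since
no principled blending rule exists for speckle.

Angulation follows the clinical protocol: the unsigned acute angle between
the distal axis (`L_d0 -> L_d1`, or any supplied segment) and the
perpendicular to the growth plate, in [0, 90] degrees. The growth-plate
direction is an input (manual annotation or phantom ground truth);
estimating it automatically from masks is deliberately out of scope. A
signed variant (`signed = TRUE`) exposes the dorsal/palmar direction.

## Contour metrics

Alignment quality against a reference contour uses the directed Hausdorff
distance and a symmetric Chamfer distance. Several Chamfer conventions
exist; this package uses the symmetric mean of linear nearest-neighbour
distances (half the sum of the two directional means), which is on the same
mm scale as the Hausdorff distance. `sum` and `squared` variants are
available behind an argument. Polylines are resampled at 0.5 mm arc steps
before metric evaluation.

## Reader-study statistics

The shipped reading table (11 samples, three readers, merged-POCUS and
X-ray angulation readings plus per-reader classification accuracies) is
processed with the following reproduction conventions:

* A no-fracture marker is valued 0 degrees wherever a number is needed.
* Per-sample references are the mean of the three X-ray readings, **rounded
  to one decimal before error computation** — this tabulation convention is
  what reproduces all six printed MAEs; with unrounded references one MAE
  shifts by 0.1 degrees.
* Samples whose reference is no-fracture are excluded from MAE and
  correlation.
* The pooled Pearson coefficient correlates the merged-POCUS absolute
  errors, pooled over readers and fracture samples, with the repeated
  reference values. This pooled definition reproduces the published
  coefficient of 0.18 and is adopted as a convention, without claiming it
  is the only possible reading.

Per-cell classification labels are not shipped: in the source table,
correctness is encoded by cell colour, which does not survive text
extraction. Only the per-reader accuracies and the majority-vote ground
truth column are distributed.

## The phantom generator

`generate_pair()` builds a vector-geometry model of a distal radius scan
window: a 60 mm horizontal diaphysis boundary, a steep metaphyseal flare
descending 4 mm to the physis point, a 3 mm physis gap, and a short separate
epiphysis boundary beyond the gap (dropped by component selection, as in
real masks). The palmar curve is the same geometry offset by one bone width
(10 mm); fracture angulation tilts the growth plate and epiphysis about the
physis by the configured angle. The moving view is mirrored (always, never,
or at random), displaced by a uniformly drawn rotation (up to 20 degrees)
and translation (up to 20 mm per axis), shifted onto a positive canvas, and
rasterized at 0.1 mm spacing with a 0.3 mm stroke. The exact composed
transform, landmarks, growth plate and angulation are recorded as ground
truth; the reported random displacement bounds apply to the drawn
perturbation, while the composed transform's translation additionally
carries the mirror/canvas bookkeeping and can be numerically larger.
`corrupt_pair()` adds Gaussian vertex jitter and contiguous-segment dropout
to emulate segmentation noise, leaving ground truth untouched.

Problem sizes used in the shipped validation: 50 phantoms for
landmark-level transform recovery, 100 configurations for landmark-accuracy
and jitter-robustness bounds, and a handful of full raster pipelines
(thinning a ~800x230 mask costs about a second).

What the phantom does *not* emulate: speckle and acoustic shadowing,
intensity information of any kind (only boundary geometry), curved or
interrupted cortices beyond the configured angulation, probe-plane
deviation between the two views, and anisotropic pixel spacing. Passing
phantom validation therefore demonstrates the geometric correctness of
extraction, optimization, fusion and measurement — not robustness to real
ultrasound image quality, which enters upstream through the segmentation.

## Known limitations

* The pipeline inherits all segmentation errors; landmark extraction fails
  loudly on fragmented or branched boundaries rather than guessing.
* The diaphysis detector assumes a roughly horizontal scan; strongly oblique
  acquisitions need a wider `horizontal_tol`.
* Constraint weights, `d` and `w` have no published reference values; the
  defaults are documented engineering choices and should be tuned per
  protocol.
* Angulation measurement requires a growth-plate direction from outside the
  package.
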