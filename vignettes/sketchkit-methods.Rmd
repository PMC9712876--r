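---
title: "Methods: drag-based proofreading, sparse-annotation surfaces, and the iterative annotation loop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drag-based proofreading, sparse-annotation surfaces, and the iterative annotation loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sketchkit)
```

This vignette is the package's account of its models and numerical choices:
what each method assumes, which parameters matter, where the design was
genuinely open and what was decided, and what the synthetic test bed does
and does not demonstrate about real data.

## Coordinate conventions

All annotations live in physical millimetres, not voxel indices, so they
survive resampling and can anchor to multi-modality data. An `image3d`
stores a voxel array in a fixed `(x, y, z)` axis order treated as an
RAS-like canonical frame; NIfTI readers reorient on load and keep the
source orientation string for provenance. Voxel indices are 0-based and
voxel *centres* sit at `origin + index * spacing`; every inclusion test in
the package (rasterization, thresholding, phantom masks) is a voxel-centre
test, which makes counts exactly reproducible by brute-force enumeration.
Oblique (non axis-aligned) orientation matrices are rejected rather than
silently resampled; DICOM series input is not supported — convert to NIfTI
first.

The slice plane of a contour is named by the axis it is orthogonal to; its
in-plane coordinates are the remaining two axes in ascending order. Open
curves and scribbles share the closed contour's geometry and differ only by
a `kind` tag, since every algorithm here treats them identically up to
closedness.

## The drag-proofreading deformation

A proofreading edit is one gesture: grab the boundary at `start`, drag it
by `motion`. The edit is realized as a free-form deformation on a regular
control lattice with 6 nodes per axis (6×6 in 2D, 6×6×6 in 3D) laid around
the start point.

**Grid placement and spacing.** The lattice is centred so the start point
has normalized local coordinate 0.5 on every axis of the central cell: the
falloff of the edit is symmetric about the grab point. The cell size
defaults to `max(|motion|, 5)` mm, so the spatial reach of an edit scales
with the gesture (a bigger pull affects a wider stretch of boundary) but
never collapses below a 5 mm cell for tiny nudges. Both are overridable;
nothing in the math requires these defaults.

**The interpolation weights.** Inside the lattice the deformation at a
point with local cell coordinate `(m, n[, l])` is the tensor product of
cubic Bernstein weights `C(3,i) (1-m)^(3-i) m^i` over the 4-node-per-axis
neighbourhood of the containing cell. Two details deserve honesty:

* *Bernstein vs B-spline.* Cubic Bernstein weights on a shared lattice are
  not the same functions as uniform cubic B-spline weights, and the
  resulting field is not continuous across cell boundaries (a per-cell
  Bézier patch with shared control points is not a spline). The Bernstein
  form is the package's reference behaviour and what all tests target; a
  `basis = "bspline"` flag switches every entry point to uniform cubic
  B-spline weights on the same neighbourhood for users who prefer the
  smooth variant. In practice the solved fields differ by a few percent in
  shape and both reproduce the drag exactly at the start point.
* *Neighbourhood at the lattice rim.* With 6 nodes there are 5 cells; a
  cell's 4-node neighbourhood is `clamp(cell - 1, 0, 2) .. +3` per axis, so
  rim cells reuse the nearest full window. The drag start always sits in
  the central cell and never sees a clamped window.

Outside the lattice the deformation is exactly zero. This hard locality is
deliberate: a proofreading tool must not move geometry the user did not
point at. The price is a (small) discontinuity at the lattice rim — the
minimum-norm solve keeps rim node vectors tiny, and no blending band is
added.

**The inverse solve.** One drag gives one linear constraint on the 16 (2D)
or 64 (3D) active node vectors: the interpolated field at `start` must
equal `motion`. The system is under-determined; the package returns the
minimum-norm (Moore–Penrose) solution, which here has the closed form
`p_k = w_k / (Σ w²) · motion` with `w_k` the basis weight of node `k` at
the start point. This choice is canonical, deterministic, exactly
interpolating, linear in the drag, and decays with the node's own weight —
the falloff a user expects from grabbing a boundary. Only the start point
constrains the solve; the intermediate stroke path is ignored.

Sequential drags compose by re-solving a fresh grid per gesture and
applying the fields cumulatively; there is no global relaxation, matching
the incremental way a human proofreads. If a drag makes a closed contour
self-intersect, the edit is returned with a warning and a
`self_intersecting` flag rather than an error — the user's next drag is the
natural undo.

## Surface reconstruction from sparse annotation

**Inter-slice ROI interpolation.** Annotating every slice of a 3D ROI is
the cost the tool exists to avoid. Given closed contours on a few
interleaved slices, each annotated slice is converted to a signed distance
field on the voxel-centre grid (negative inside, distance to the polygon
otherwise), fields are interpolated linearly along the slice axis, and
voxels with negative interpolated distance form the solid mask. The choice
of SDF blending over vertex-correspondence morphing was open; SDF blending
was picked because it needs no correspondence matching, tolerates shape
change between slices, and is *exact on annotated slices* — there the mask
is computed from the drawn polygon's inclusion test itself, so proofreading
a drawn slice is never undone by reconstruction. Slices outside the
annotated range stay background: the method does not extrapolate caps
beyond the outermost drawn contours, which is the main source of the
residual Dice gap on sphere phantoms (missing polar caps). The boundary
mesh is lofted from per-slice zero isolines (via `grDevices::contourLines`)
resampled to a fixed ring size, with centroid-fan caps; only the largest
isoline per slice is lofted, so multi-component ROIs get a correct mask but
a single-component mesh — a known limitation.

**Fissure-like sheets.** Thin separating sheets sketched as open curves on
a few slices are modeled as a single-valued height field over the plane
orthogonal to a user-chosen axis, interpolated with a thin-plate spline
(`r² log r`) plus affine term, solved as the standard augmented symmetric
system with base R `solve()`. Interpolation is exact by default; a `ridge`
parameter trades exactness for smoothing on sloppy sketches. TPS was chosen
over other radial kernels because it is parameter-free and reproduces
affine sheets exactly — a flat fissure stays flat. Duplicate planar sample
locations are averaged (with a warning); centres collinear in the plane
make the affine block rank-deficient and raise an explicit error. A general
implicit (folded) surface mode is out of scope: anatomical fissures are
single-valued along a well-chosen axis at annotation scale. Evaluation
beyond the sketched region is polynomial-dominated extrapolation; meshing
clips to a caller-supplied bounding box for exactly that reason.

**Threshold extraction.** The quantification step is a pure predicate:
voxels inside the ROI whose intensity is strictly above (or below) the
cut, with count and `count × voxel volume` reported. Strict inequality is
documented behaviour, so counts are exactly reproducible by a triple loop.
Artefact masking or any preprocessing upstream of the predicate is the
caller's business, and deliberately not bundled.

## The plugin exchange protocol

An extension module is a text configuration file plus a program. The INI
dialect is defined by this package: a `[module]` section (`name`, `type`,
`program`), `[input.<key>]`/`[output.<key>]` parameter sections (`kind`,
`required`, `default`, `choices`) and ordered `[widget.<n>]` sections
(`widget`, `label`, `binds`). Parsing is strict — unknown keys fail with
line numbers, widget bindings must reference declared inputs, a `drop_menu`
must bind a `choice` — because configuration typos should fail at import,
not mid-run. The widget model is parsed and validated but never rendered
here; it exists so a GUI layer can be generated from the same file.

Data exchange is loose coupling in the literal sense: the host writes
images and masks as NIfTI, meshes as PLY, annotation sets as JSON and
scalars as a `params.json` with sorted keys (staging is byte-deterministic)
into a fresh timestamped work directory; the program is invoked with that
directory as its *single argument*; outputs are read back from agreed file
names recorded in `manifest.json`. No shared memory, no linkage, no
language assumption — the test suite drives one stub plugin that is a plain
`/bin/sh` script. Programs ending in `.R`, `.py`, `.sh` are dispatched to
their interpreters; anything else is executed directly. The default
timeout is 600 s; work directories are never reused, so a failed run's
files remain inspectable. Nonzero exit, timeout and missing output are
three distinct condition classes, each carrying the last lines of the
captured logs.

## The iterative annotation loop

The loop automates the annotate–train–predict–proofread cycle: train on the
labeled pool, predict a batch from the unlabeled pool, hand predictions to
a proofreader, move the corrected pairs into the labeled pool, repeat. The
open orchestration questions were decided as follows: batches are taken in
dataset (FIFO) order with no active-learning ranking; training uses the
whole labeled pool with no internal validation split; the stopping rule is
a fixed iteration budget or a mean-Dice improvement below ε = 0.005,
whichever first; and the adapter contract passes the full labeled pool each
time, so an adapter may retrain from scratch or finetune — the shipped
reference adapter retrains.

**Simulated proofreading.** Headless experiments need a stand-in for the
human. `simulate_proofread` flips `round(effort · n)` of the `n` mislabeled
voxels toward the reference, worst first, where "worst" is the distance to
the reference boundary (computed by exact nearest-neighbour against the
boundary voxel set; ties broken by ascending linear index so the operation
is fully deterministic). Effort 1 reproduces the reference exactly, effort
0 is a no-op, and corrected Dice is non-decreasing in effort. The flipped
voxels' mean boundary distance is reported as the correction magnitude, a
proxy for how far the human had to drag.

**The reference adapter and why retraining helps.** The desk-scale pool
consists of ellipsoid "organ" phantoms whose intensities carry one of four
discrete global offsets (−30, −10, +10, +30 around background 100 /
foreground 140, voxel noise SD 12), emulating data pooled from different
acquisition protocols. The reference adapter is a deliberately weak
intensity classifier: per training image it stores (background level ≈
image median, optimal threshold = class-mean midpoint); per test image it
looks up the threshold of the nearest-background training image, thresholds,
and majority-filters (3×3×3). Its accuracy on a protocol therefore depends
on having *seen* that protocol in training — and because the labeled pool
only ever grows, protocol coverage, and with it held-out accuracy, improves
monotonically across iterations. This is the mechanism the loop is supposed
to exhibit (later models beat earlier ones), realized structurally rather
than by statistical luck. An earlier candidate design — estimate one global
threshold, let its variance shrink with pool size — was discarded: with
small foreground fractions the Dice-optimal threshold is biased away from
the class midpoint, so better estimation of the midpoint does not translate
into better Dice, and no learning curve appears.

The same loop runs with the adapter as a pair of external programs through
the plugin protocol (`plugin_adapter`); the suite exercises this with
Rscript stubs to show no in-process model coupling is required.

## What the phantoms do and do not show

All tests run on generated data with analytic ground truth: spheres, cubes
and ellipsoids (centre-inclusion masks), a hot-block phantom with an exactly
known supra-threshold count, an analytic `sin·cos` sheet sampled as slice
curves, and the protocol-offset blob pools. Noise is additive Gaussian on
intensities only; geometry is never noisy. Phantoms are bit-reproducible
from their spec (seed included), which every oracle test relies on.

This test bed establishes algorithmic correctness — exactness, locality,
convergence with annotation density, protocol fidelity — not clinical
performance. Real anatomy has texture, partial-volume boundaries,
non-ellipsoidal shapes and artefacts that no phantom here emulates; passing
these tests says the machinery is right, not that a particular organ will
segment well. Problem sizes were chosen to keep the full suite fast on one
CPU: 64³ volumes for the reconstruction studies, 32³ for the loop pools
(40 training + 20 held-out images per seed, 10 seeds), 128-vertex contours
and ~1100-vertex spheres for the deformation studies. The quantities the
acceptance script reports are computed at exactly these sizes.

## Numerical choices, collected

* Even-odd (crossing-parity) voxel-centre inclusion for rasterization;
  points exactly on an edge are measure-zero on the half-integer-offset
  fixtures used to pin exact counts.
* Closed contours must be simple; the check is an O(n²) segment
  intersection scan, fine at annotation sizes.
* Serialization writes doubles at full precision (`digits = NA`), giving
  round trips well below the 1e-9 mm documented tolerance; integers are
  exact.
* The inverse-interpolation solve is exact to machine precision at the
  start point (closed form, no iteration); the 1e-8 tolerance quoted in
  tests is a safe ceiling, not the observed error (~1e-15).
* TPS systems are solved densely; with the pure interpolant, near-duplicate
  centres make the system ill-conditioned — hence duplicate averaging at a
  1e-6 key tolerance and the explicit collinearity error.
* Degenerate (≤1e-12 mm²) triangles are rejected by the mesh constructor
  and pruned from lofted caps before construction.
* `simulate_proofread` breaks distance ties by ascending linear voxel
  index; `round(effort · n)` uses half-up rounding so effort 0.5 on 100
  discrepancies flips exactly 50.

## Known limitations

Oblique NIfTI orientations and DICOM input are rejected, not resampled.
The lofted ROI mesh handles one boundary component per slice. Fissure
surfaces must be height fields along some axis. The FFD field is
discontinuous at cell and lattice boundaries under the reference Bernstein
weights (use `basis = "bspline"` for a smooth field at the cost of
departing from the reference form). The plugin protocol trusts the
program's outputs — it validates presence and format, not plausibility.
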