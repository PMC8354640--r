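---
title: "Methods: quantifying heart-tube twisting from cell tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying heart-tube twisting from cell tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotwist)
```

## The measurement problem

During zebrafish cardiac looping (~28–38 hpf) the heart tube bends in a
plane and simultaneously twists: the ventricle and atrium rotate in
opposite directions about their own long axes, around the AV canal acting
as a hinge. Raw cardiomyocyte displacement vectors confound three
motions — whole-heart drift, planar bending of the tube, and axial chamber
rotation — and only the last one constitutes torsion. The pipeline
separates them with two exact geometric reductions followed by a simple
per-cell angular statistic.

### Rooting (drift removal)

Every frame is translated so the AV-canal centroid (arithmetic mean of the
AV cells' positions) lies at the origin. Any per-frame global translation
of all cells is thereby cancelled exactly; the package asserts invariance
to 1e-9 µm in its tests.

### Computational unfolding (bending removal)

Per frame, two axes are built: from the AV centroid to the ventricle
centroid, and from the AV centroid to the atrium centroid. Each chamber's
cells are then rotated rigidly about the origin by the *minimal* rotation
(axis ∝ u×v, Rodrigues form) that maps the frame's chamber axis onto the
**first frame's** axis. Aligning every frame directly to the first frame —
rather than chaining frame-to-frame alignments — avoids compounding
rotation error across ~45 steps. AV-canal cells are translated but never
rotated: they are the hinge. After unfolding, all frames share the
first-frame axes (checked to 1e-9), and a pure hinge-angle change (planar
buckling) is removed exactly: a synthetic bending-only movie returns every
atrium cell to its frame-0 position to machine precision, and its apparent
chamber rotation is ~0°. This is the property that justifies interpreting
the remaining signal as twisting rather than buckling.

### Rotation statistic

For a cell present at two consecutive observed frames, both positions are
projected into the plane through the origin perpendicular to the chamber's
(shared, first-frame) axis, and the signed angle α between the projections
is taken via `atan2`, positive counterclockwise viewed from the axis tip
(right-handed, degrees, range (−180, 180]). Per inter-frame interval:

* `mean_alpha` — unweighted mean of α over contributing cells (cells
  absent from either frame simply do not contribute);
* `omega = mean_alpha / Δt` with Δt the *actual* timestamp difference
  (frame periods of "approximately 13 min" jitter in practice);
* `cum_angle` Θ(t) — running sum of the per-interval means, Θ(t₀) = 0.

The twisting angle is T(t) = Θ_atrium(t) − Θ_ventricle(t); the twisting
velocity is reported as tumbling-window means of ω_atrium − ω_ventricle.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_points` | 15 | frames | track-selection threshold; boundary inclusive (a 15-point track is kept) |
| `window_hours` | 1.5 | h | tumbling-window width for velocity summaries (~7 intervals at 13-min frames) |
| `eps_proj` | 0.5 | µm | minimum perpendicular distance from the axis for α to be defined; below roughly half a voxel (voxels ≥ 0.889 µm) the perpendicular offset is noise-dominated, so such cell/frame pairs are skipped and logged |
| `gap_policy` | `"scale"` | — | a track pair spanning missing frames contributes its angle spread over the spanned grid intervals in proportion to their durations (total contribution = the measured angle); `"drop"` ignores gapped pairs |
| `frame_period_hours` | 13/60 | h | nominal acquisition period; used only to synthesize `t_hours` when a file lacks explicit times |

Numerical choices: all geometry in double precision; angles in degrees
throughout; the antiparallel case of the minimal rotation (u·v < 0,
‖u×v‖ < 1e-9) rotates 180° about the component of global +z perpendicular
to u, falling back to +x when u ∥ z — an arbitrary but fixed, documented
tie-break that real axis motion never reaches.

### Sign conventions

The mathematical convention (counterclockwise-positive from each axis tip)
is the default and is what the synthetic ground truth is expressed in.
`view_from_outflow = TRUE` re-signs the reported chamber series to a
single biological viewpoint at the heart's outflow: the ventricle axis
points toward the outflow (sign kept) while the atrium axis points away
(sign flipped). The twisting series is always computed in the mathematical
convention so that its ground-truth arithmetic (ω_A − ω_V integrated over
time) holds regardless of viewpoint.

### AV-canal series

The hinge has no axis of its own, and which chamber axis its (erratic)
rotation values should be measured about is a genuinely open choice; the
pipeline computes the AV-canal series twice, once about each chamber's
reference axis, and reports both rather than guessing.

### Additivity across splits

Θ is a sum of per-interval means, so splitting a movie at an observed
frame and summing the parts reproduces the whole *provided both parts are
unfolded against the same reference axes*; `root_and_unfold(ts, reference
=)` exists for exactly this, and the equality is tested to 1e-9. Without a
shared reference each part would align to its own first frame and the
per-interval angles would differ minutely.

## What the synthetic generator emulates — and what it does not

`generate_heart()` builds a two-chamber tube: cylinders for ventricle
(radius 25 µm, length 60 µm), AV canal (12 µm, 20 µm) and atrium (25 µm,
60 µm) joined end to end, with 60/20/60 cells placed on the lateral
surfaces (the myocardium is an epithelial shell, so cells are surface
points). Defaults emulate the acquisition regime the analysis targets: 46
frames at 13/60 h (a 9.75 h movie) and 1 µm isotropic Gaussian noise.
Composition order per frame is fixed and documented: spin about the
instantaneous segment axis, then bending (the atrium swinging about the +z
hinge axis; the ventricle axis stays fixed in space, one hinge degree of
freedom sufficing to emulate planar buckling), then drift, then noise.
Drift and dropout default to 0 — no magnitudes exist to emulate, so
scenarios that exercise them set them explicitly.

Cells are placed as antipodal pairs (φ and φ+π at the same axial
coordinate; AV-canal pairs also mirrored axially). Marginally each cell is
still uniform on the surface, but the empirical region centroids then lie
exactly on the segment axes and the hinge centroid exactly at the bend
pivot. This makes the noise-free pipeline identities exact (recovery of
imposed Θ, and bending-only returning frame-0 positions, both to machine
precision) instead of carrying a finite-sample axis-wobble bias of order
1°, which would conflate generator sampling error with pipeline error in
the recovery tests.

Deliberately **not** simulated: cell division, ingression or second-heart-
field addition (looping proceeds without it in explant and inhibitor
experiments), chamber ballooning/growth, cell-shape changes, and any
mechanical tissue model. Passing the recovery tests therefore shows the
*estimator* is correct for rigid-spin kinematics under noise, dropout,
drift and bending — not that real hearts are rigid cylinders. On real
data, non-rigid deformation and region mis-labelling add error modes the
synthetic suite does not probe.

## Morphometrics

The roundness of a cell outline is the Fiji-style descriptor
4·A/(π·major²), with the major axis taken from the best-fit
(second-moment) ellipse of the enclosed region; a circle scores 1 and an
a:b ellipse scores b/a. The perimeter-based circularity 4πA/P² is
available behind `method = "circularity"` since the two are often
conflated and report differently on irregular outlines. Second moments
are computed by exact shoelace-type boundary integrals rather than by
sampling the enclosed region: the result is deterministic and matches an
independent fan-triangulation covariance oracle to 1e-6, which a Monte
Carlo estimate could not. The straightness index is chord length over arc
length of the boundary polyline (taken as given; no surface geodesics are
computed). The AV-canal angle is the angle between the two chamber axes
after projection into a viewing plane (default ventral, normal +z) — an
operational definition chosen here, since only a figure inset illustrates
the measurement in the source material this package's analyses parallel.

## Statistics

Group comparisons wrap the standard machinery: `wilcox.test` (exact for
untied samples of ≤8 per group, normal approximation with continuity and
tie correction otherwise; all-tied data degenerate to p = 1),
equal-variance `t.test` with defined zero-variance limits, and one-way
ANOVA via `aov`. Bonferroni adjustment is min(1, m·p) with m always the
explicit number of requested comparisons — nothing is inferred about
which comparison family was intended. The test suite verifies the exact
3-vs-3 complete-separation p of 0.1 by enumeration and that the rank-sum
test holds its nominal 5% size (empirically within [0.03, 0.07] over 1000
null replicates at n = 10 per group).

## Problem sizes

The packaged analyses and tests run the full pipeline on 140-cell,
46-frame synthetic hearts (single-core seconds per run); the null
calibration uses 20 seeds and the statistical size checks 1000 replicates.
These sizes give sub-degree Monte Carlo error on the quantities asserted
and keep every check cheap enough to run routinely.

## Known limitations

* Region membership is fixed per track (taken from the track's label, as
  assigned at the start of its trace); cells crossing region boundaries
  mid-movie are not re-assigned.
* The chamber axis is a centroid construction; strongly asymmetric cell
  sampling of a chamber surface biases the axis and hence the measured
  rotation, an effect the antipodally-symmetric generator intentionally
  excludes (see above).
* `eps_proj` trades bias for variance near the axis; cells spiralling very
  close to the axis are dropped per frame pair rather than smoothed.
* No trajectory smoothing or Kalman filtering is applied; noise enters ω
  directly and is reduced only by cell- and window-averaging.
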