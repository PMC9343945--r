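---
title: "Deriving a human-body-model lineup by landmark-driven morphing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a human-body-model lineup by landmark-driven morphing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbmforge)
```

## The problem

Finite-element human body models (HBMs) for crash biomechanics are
expensive to build: a single high-quality hexahedral mesh of an average
female occupant takes years of geometry work.  A *lineup* of such models —
female and male, seated occupant and standing vulnerable road user — can
instead be maintained as one base model plus derivative node sets: every
model shares all solver include files (elements, parts, materials,
contacts) and differs only in the include defining the node coordinates and
a handful of parameters.  Updates to the base propagate to the whole lineup
by re-running the morph.

`hbmforge` implements that factory: the modular keyword-deck layer, the
landmark-driven radial-basis-function (RBF) morph with its sequential
staging, the anatomical target-construction rules, mesh-quality
classification, mass calibration, and the blunt-impact validation
machinery (deck emission and signal postprocessing).  The explicit FE solve
itself is out of scope; an external solver produces the time histories that
the postprocessing side consumes.

Units are mm–ms–kg everywhere: forces in kN, stresses in GPa, densities in
kg/mm³, speeds in mm/ms (numerically equal to m/s).

## Keyword-deck layer

Decks are read and written in an LS-DYNA-style keyword format.  The reader
understands `*NODE`, `*ELEMENT_SOLID`, `*ELEMENT_SHELL`,
`*ELEMENT_DISCRETE`, `*PART`, `*PARAMETER`, `*INCLUDE`, `*KEYWORD` and
`*END`; every other card is preserved verbatim and re-emitted unchanged, so
material and contact definitions pass through untouched.  Two dialects are
accepted per line: fixed-width (8-character integers, 16-character floats
on `*NODE`) and comma-separated; the writer defaults to fixed-width.  A
strict fixed-width slice is tried first, with a free-whitespace fallback,
because field widths of third-party decks vary in practice.

The writer formats each coordinate as the shortest decimal string that
reparses to the same double and fits the field, falling back to the most
precise fitting string.  This rule is idempotent — write, parse, write
reproduces identical text — which makes emitted decks a fixed point of the
I/O layer and keeps diffs between lineup members meaningful.  Node and
element ids are never renumbered by any operation: derivative models must
share all includes, so the morph only ever replaces coordinates.

Region tags and densities ride on a `$HBMFORGE region=... density=...`
comment line inside `*PART` cards.  Comment lines are legal in the format,
so decks remain valid for any downstream consumer; plain decks simply parse
with those columns `NA`.

## The morph

The deformation field is interpolated from landmark correspondences: source
landmarks on the base model's template mesh (skin plus bone surfaces), and
target landmarks constructed per derivative.  The interpolant is

$$ f(x) = c_0 + C\,x + \sum_i w_i\, \lVert x - x_i \rVert^3 $$

— the triharmonic kernel $r^3$ in 3-D with a full affine term, solved with
the usual side conditions $\sum_i w_i = 0$, $\sum_i w_i x_i = 0$.  The
kernel choice is a design decision: $r^3$ gives smooth volumetric
deformation, and the affine term makes the interpolant reproduce any affine
target map *exactly*, which is the property the test suite leans on
(identity, translation, anisotropic scaling are all affine).  The system is
solved in normalized coordinates (centred, scaled by the mean landmark
spacing); without this the saddle system mixes $r^3 \sim 10^8$ kernel
entries with $O(1)$ polynomial entries and becomes numerically singular for
mm-scale meshes.

Source landmarks closer than 1e-6 mm are merged with averaged targets
before solving.  An optional ridge (default `1e-10 ×` mean squared
normalized spacing, i.e. ~1e-10) guards against near-duplicates that
survive the merge; passing `ridge = 0` gives strictly exact interpolation,
with landmark residuals below 1e-8 mm.

### Sequential stages and exterior nodes

Fitting one interpolant to every template landmark means inverting a matrix
of the size of the template mesh, so the morph is staged: extremities
first, then torso and head.  Continuity across stages comes from *exterior
nodes*: boundary nodes morphed by an earlier stage are saved and re-used by
later stages as extra landmark pairs (source = base position, target =
morphed position).  A `morph_plan` is an ordered list of stages, each
naming its move set, its landmark labels and the node ids it saves; every
model node must belong to exactly one stage's move set, which the engine
validates.  Exterior-node landmarks enter the later solve with the same
weight as template landmarks — the interpolant passes through them exactly,
which is precisely the continuity requirement.

### Support surfaces

Joints that rotate far between postures (hip, knee, elbow) would tear the
interpolated field if the two adjacent bones were simply given their rigid
targets.  Pre-morphed *support surfaces* bridge the gap: auxiliary point
sheets around the joint whose targets blend the two adjacent bone
transforms with inverse-distance weights to the two bone surfaces
(normalized to sum to one at every point).  The blend is a design decision
— any partition-of-unity weighting that respects the near bone would do —
and the weights-sum-to-one property is asserted in the tests.  Patches of
poor elements near large-rotation joints are *reported* (worst-element
lists per metric), mirroring a workflow where remaining defects are fixed
by hand; the package deliberately performs no automatic node repair or
contact de-penetration.

## Anatomical target construction

* **H-point**: centre of a least-squares sphere fitted to femoral-head
  surface points (algebraic linear fit; the test oracle is an independent
  nonlinear refit).  Model origin: at the H-point for seated models, at the
  foot sole directly below it for standing models; ISO axes (x forward, y
  left, z up).
* **Stature scaling**: bones not governed by statistical shape models are
  volumetrically scaled by the outer-surface dimensions.  The scapula uses
  the male/female stature ratio as a percent (1750/1620 mm → 108%); the
  clavicle is scaled to match the target distance between the
  sternoclavicular and acromioclavicular joints.  Anchors are a design
  decision (scapula about its centroid, clavicle about the sternoclavicular
  joint) since only the factors are prescribed.
* **Spine re-definition**: the thoracic/lumbar curve is rebuilt from four
  joint landmarks (OC/C1, C7/T1, T12/L1, L5/S1) under the assumption that
  the spine follows the back-skin curvature in between.  The construction
  offsets the skin polyline inward along its in-plane normal by the
  skin-to-spine distance measured at each joint (linearly interpolated in
  arc length between joints), then corrects the curve so it passes exactly
  through the four landmarks.  Vertebrae are placed at their preserved
  arc-length fraction between bounding joints and rotated by the minimal
  rotation between old and new tangents — axial twist is deliberately
  preserved, since nothing constrains it.  The final curve is kept as the
  corrected dense polyline rather than re-smoothed: with a profile sampled
  at mesh resolution the difference to a spline fit is below mesh
  tolerance, and the polyline keeps arc-length bookkeeping exactly
  consistent between source and target (the fixed-point property —
  re-shaping a spine onto its own curve moves nothing — holds to 1e-6 mm).
* **Standing (VRU) variants**: skeletal groups are rigid reorientations of
  the occupant skeleton; the pelvis rotation about the y-axis through the
  hip centre is 42° for the female and 39° for the male, and the ribcage
  moves together with the thoracic spine under one transform.
* **Pre-impact transforms**: tabulated (z_rot, y_rot) pairs are applied as
  rotation about global z, then global y, both through the origin — the
  column order read as application order.  The tables only list angles, so
  the composition convention is a documented decision.

## Mesh quality

Three metrics with deliberately simple, oracle-checkable definitions
(parity with any one commercial preprocessor is not claimed):

* scaled Jacobian — minimum over corner evaluation points of the
  normalized corner-edge triple product (corners, not Gauss points);
* aspect ratio — longest over shortest element edge;
* warpage — angle between the two corner-triangle normals of a quad,
  maximized over the two diagonal splits.

The 100% failure levels are 0.3 (Jacobian), 12 (aspect) and 30°
(warpage, shells only); an element fails if any applicable metric is out
of bounds.  All three metrics are invariant under rigid motion and uniform
scaling.  Pentahedra are measured through their wedge corners and edges;
warp applies to quads only.

## Mass calibration and added mass

Flesh starts at a homogeneous baseline density of 1e-6 kg/mm³.  Because of
voids the model would come out light, so the flesh density is re-solved per
region: `ρ = (target − non-flesh mass) / flesh volume`, with whole-body
targets 62 kg (female) and 77 kg (male).  A verification pass recomputes
masses and asserts every target within 0.1%.  Targets below the non-flesh
mass are rejected — density scaling cannot remove mass.  Because the four
lineup members do not share exactly the same flesh volume, one multiplier
per (sex, posture) pair rescales the solved densities; the package applies
these as per-variant multipliers on top of the region solve, which is one
of the two readings the source material admits (the other being a single
whole-body factor) and the more general of the two.

Solid volumes use a six-tetrahedron decomposition about the 1–7 diagonal
(exact for parallelepipeds); shell masses are area × thickness × density.

Explicit mass scaling: per element, the critical timestep is the
characteristic length over the dilatational wave speed
`c = sqrt(E(1−ν)/((1+ν)(1−2ν)ρ))`.  Characteristic length conventions are
`volume / largest face area` for hexahedra and `area / longest edge` for
shells — standard explicit-code conventions; any consistent choice works
because the acceptance checks are closed-form (an element at half the
target timestep gains exactly three times its mass, since density scales
with the square of the timestep ratio).  Added mass is monotone in the
target timestep and is reported per part, so concentration in thin stiff
parts (fibula-like geometry) is visible directly.

## Impact validation machinery

The blunt-impact catalog covers eight case families: frontal torso hub
(⌀152 mm, 6.3/14.3 m/s), back hubs at T1/T6 (23.4 kg) and T8 (97.5 kg)
with stroke limiters, the 25 mm abdominal bar (48 kg, 6.3/9.2 m/s), the
150×80 mm shoulder plate from both sides, and lateral hubs at thorax,
abdomen and hip in standing posture.  Emitted decks contain the
pre-rotated body model, a rigid shell impactor aligned with the impact
landmark, the initial-velocity card, the contact card (static friction
0.3, viscous damping 20, SOFT 2, SBOPT 3, DEPTH 5), and a minimum-timestep
control of 0.3 µs; no gravity and no constraints on the body.  The
impactor always travels along global −x and the *body* is rotated, so the
0°/90° direction convention describes the body-frame impact direction.
Stroke-limiter stiffness and gap are config inputs (default 1 kN/mm,
50 mm stand-off) since only their existence, not their values, is
prescribed.

### Postprocessing

Solver histories are expected at a 0.1 ms output interval.  Deflection
measures per case type: sternum-to-T8 relative displacement projected on
the impact axis (front/back), impactor-centre travel (lateral),
acromion-to-acromion distance change (shoulder), impactor-to-L3 relative
displacement (abdomen); compression positive.  The projection onto the
impactor travel axis (rather than the displacement resultant) is a
documented choice where the wording "change in displacement between" is
ambiguous.  All relative measures are exactly invariant under a global
rigid translation of the histories.

Channel-class filtering follows the crash-signal convention: a two-pole
low-pass with the class's published difference-equation coefficients
(`wd = 2π · CFC · 2.0775`, bilinear-prewarped), run forward and backward
for zero phase — a four-pole phaseless response overall.  Ends are
mirror-padded by 10 ms and each pass starts at steady state for its first
sample, so DC gain is exactly 1 and edge transients stay out of the
signal.  The analytic four-pole magnitude (with bilinear prewarping) is
exposed as `cfc_expected_gain()` and doubles as the attenuation oracle: a
sinusoid at 10× the class frequency comes through within 2% of it.

Force–deflection curves pair the two channels over the first ~20 ms of
the impact, preserving sample order (no sorting of non-monotone
deflection).  The corridor score — the fraction of samples inside the
linearly interpolated experimental band — is introduced here as a
quantitative stand-in for visual corridor comparison; corridors themselves
are external inputs.

## The synthetic fixture

`make_fixture_body()` builds a deterministic hex-meshed "body": a box
torso with an internal spine column, two L-shaped legs (thigh forward,
shank down — schematic seated posture) with internal bone columns, torso
skin shells, a region partition, source landmarks (boundary-node skin plus
per-bone sets), and a two-stage morph plan with exterior-node bookkeeping
at the hip interfaces.  Default sizes: 60 mm elements, 152 solids, 16
shells, 300 nodes — the whole test suite runs in well under a minute on
one CPU, and every generated element passes the quality thresholds by
construction.

The fixture emulates the *mechanics* of the real inputs — shared-include
structure, landmark/template correspondence, staged morphing across
a large joint rotation, mass bookkeeping — not their anatomy.  Passing
tests therefore demonstrate the correctness of the machinery (exactness,
conservation, invariances, closed forms), not biofidelity of any real
model; geometry-bound steps such as statistical-shape-model prediction of
landmarks are out of scope and landmarks are always inputs.

Variant targets: `scaled_male` applies an anisotropic scaling (default
1.08/1.05/1.08, stature-ratio flavoured) to all landmarks — a pure affine
map, so the morph result is checkable against the closed form;
`standing` rotates each limb rigidly about hip (90°) and knee (−90°) and
adds inverse-distance support sleeves at both joints; landmarks in a
one-element transition zone around each joint are left out and covered by
the sleeves instead.  The history generator emits analytic motions
(rigid drift + `A(1−cos ωt)/2` deformation + optional seeded noise) with
the exact deflection and force channels recorded alongside; the lateral
case's impactor history carries no drift because its measure is the
impactor's own travel.

## Numerical choices, at a glance

| Choice | Value | Why |
|---|---|---|
| RBF kernel | $r^3$ + affine | exact affine reproduction, smooth in 3-D |
| RBF normalization | centre + mean spacing | conditioning of the saddle system |
| default ridge | 1e-10 × mean sq. normalized spacing | near-duplicate guard, ~machine-level bias |
| landmark merge tolerance | 1e-6 mm | below mesh tolerance |
| fixed-width fields | 8 / 16 characters | the common wide deck format |
| coordinate text | shortest exact, else most precise fitting | bit-stable roundtrip |
| quality thresholds | 0.3 / 12 / 30° | the lineup's 100% failure levels |
| baseline flesh density | 1e-6 kg/mm³ | calibration starting point |
| mass-target tolerance | 0.1% | verification band of the density solve |
| CFC pad | 10 ms mirror, steady-state start | exact DC, no edge transients |
| analysis window | 20 ms | first impact phase |

## Limitations

The package generates and checks models; it does not solve them, and no
claim is made that emitted decks are complete solver inputs (materials and
section cards pass through opaquely or as stubs).  Quality metrics use one
standard definition each, which may differ in detail from any given
preprocessor's variant.  Manual mesh repair and contact de-penetration are
reporting-only.  The spine construction assumes an approximately planar,
densely sampled back profile, and the cervical-spine repositioning used in
seated postures is data-bound and not reproduced.
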