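# hbmforge

A lineup factory for finite-element human body models (HBMs).  Instead of
maintaining four independent crash-simulation models (average female and
male, seated occupant and standing vulnerable road user), a lineup keeps
**one base model** and derives the others by landmark-driven mesh
morphing, so that every member shares all solver include files except the
node coordinates and a few parameters.  `hbmforge` implements everything
around that idea, for model developers and crash-biomechanics researchers:

* **Keyword-deck I/O** — read/write modular LS-DYNA-style decks
  (fixed-width or comma dialect), resolve include graphs, assemble
  variants that differ only in their nodes include, and diff lineup
  members structurally.  Unknown cards pass through verbatim.
* **Morph engine** — radial-basis-function interpolation of the
  deformation field from source/target landmarks,

  `f(x) = c₀ + C x + Σᵢ wᵢ ‖x − xᵢ‖³`,

  with a full affine term and side conditions (`Σ wᵢ = 0`, `Σ wᵢ xᵢ = 0`),
  run as sequential per-region stages with exterior-node bookkeeping and
  pre-morphed support surfaces across large joint rotations.  The affine
  term makes any affine target map reproduce exactly; with zero ridge the
  landmark residual is below 1e-8 mm.
* **Anatomy rules** — H-point from a least-squares sphere fit to the
  femoral head, ISO coordinate conventions for seated and standing
  origins, spine-curve re-definition from four joint landmarks and the
  back-skin profile, volumetric bone scaling, the stature-ratio and
  clavicle scaling rules, and rigid skeletal reorientation for standing
  variants (pelvis rotation 42°/39° about the hip).
* **Mesh quality** — scaled Jacobian, aspect ratio and warpage with
  pass/fail classification at the 0.3 / 12 / 30° failure levels, plus
  base-vs-derivative morph reports with worst-element lists.
* **Mass calibration** — region-wise mass accounting, flesh-density
  solving to hit 62 kg / 77 kg whole-body targets within 0.1%, per-variant
  (sex, posture) density parameters, and explicit-timestep added-mass
  estimation (density × (Δt/Δt_crit)² scaling).
* **Impact validation** — a machine-readable blunt-impact case catalog
  (front/back torso hubs, abdominal bar, shoulder plate, lateral hubs),
  emission of impact decks with the stated contact settings (friction 0.3,
  viscous damping 20, SOFT 2, SBOPT 3, DEPTH 5, minimum timestep 0.3 µs),
  phaseless CFC-class filtering, case-specific deflection channels,
  force–deflection curves and corridor scoring.
* **Fixtures** — a deterministic generator of small hex-meshed body-like
  models, landmark sets, morph targets and analytic time histories, so the
  whole pipeline is testable without a commercial solver.

Units are mm–ms–kg throughout (forces kN, densities kg/mm³, speeds
mm/ms = m/s).

## Worked example

Derive a standing variant of the synthetic base body, check mesh quality,
and assemble the variant deck:

```r
library(hbmforge)

fx <- make_fixture_body()           # seated base model + landmarks + plan
fx$assembly
#> Keyword-deck model assembly (mm-ms-kg)
#>   nodes: 300   solids: 152   shells: 16   discretes: 0
#>   parts: 11   parameters: 1   opaque card blocks: 0
#>   includes: nodes.k [nodes], elements.k [region-definition], parts.k [region-definition]

tg  <- make_fixture_targets(fx, "standing")   # rigid limb targets + support sleeves
res <- morph_derivative(fx$assembly, tg$plan, tg$source, tg$target)
morph_report(fx$assembly, res$assembly)
#> Morph quality report
#>   max nodal displacement: 516.140 mm (300 nodes moved)
#>   failing elements: base 0 -> derivative 0

variant <- assemble_variant(fx$assembly, res$nodes)
assembly_diff(fx$assembly, variant)$structure_identical
#> [1] TRUE
```

The hip rotates 90°, moving distal nodes by half a metre, yet no element
falls below the quality thresholds and the variant shares every table with
the base except node coordinates — the property the lineup design rests
on.  Postprocessing works the same way on synthetic or solver histories:

```r
h  <- make_fixture_histories("front")          # analytic impact histories
d  <- deflection_channel("front", h$histories) # sternum-T8 on the impact axis
f  <- cfc_filter(h$force, 180)                 # phaseless class filter
fd <- force_deflection(f, d)                   # first 20 ms
cor <- corridor(seq(0, 30, 5), 0.04 * seq(0, 30, 5), 0.06 * seq(0, 30, 5))
corridor_score(fd, cor)$score
#> [1] 0.9502488
```

i.e. 95% of the filtered force–deflection samples lie inside this
(synthetic) experimental corridor band.

A thin command-line front end is installed under `inst/cli/hbmforge`
(`deck-cat`, `qa`, `mass` subcommands over a resolved main deck).

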