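---
title: "Geometric screening of stereotactic cone collisions: model, numerics and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric screening of stereotactic cone collisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conearc)
```

## The screening problem

Cone-based intracranial SRS combines non-coplanar arcs (large couch
kicks) with a collimator cone that sits only ~250 mm from isocenter.
Whether a planned arc physically clears the couch and the patient must be
verified in the room, but discovering a collision there forces
replanning, and avoiding the risk by restricting couch angles costs dose
falloff. `conearc` answers a narrower question at planning time: *given a
one-time survey of the machine and a conservative envelope around the
patient's head, does each planned arc keep clearance, come close, or
collide?* Everything in the package serves that question; none of it
replaces the in-room check.

## Geometry and assumptions

All computation is in IEC 61217 fixed coordinates for a head-first supine
patient: x to the patient's left, y superior, z anterior, isocenter at
the origin, lengths in mm (strictly: in whatever unit the planning system
reports shifts in — consistency is what matters), angles in degrees at
every public interface.

Five components are modelled, each as a single convex primitive obtained
from a unit solid (box of side 1, cylinder of diameter and height 1,
sphere of diameter 1, all centred at the origin) by the **fixed chain
scale → translate → rotate**:

* **cone** — cylinder, diameter `cod`, spanning z ∈ [`cad`, `had`];
* **gantry head** — cylinder, diameter `hod`, z ∈ [`had`, `had + ht`];
* **couch head / couch body** — boxes of thickness `cht` whose shared top
  plane sits `chad` below the safety-zone centre, abutting exactly at the
  head's inferior edge `chie` (no gap, no overlap);
* **safety zone** — box or ellipsoid with extents `szr+szl`, `szs+szi`,
  `sza+szp` about its commissioned centre. This is the localization frame
  that fully contains the head, so it over-covers every real patient: a
  deliberate conservatism.

Gantry-mounted solids carry one rotation about y, couch-mounted solids
one rotation about z; the rotation is applied **after** translation, so
couch kicks pivot the whole patient assembly about the vertical axis
through isocenter and gantry rotation sweeps the beam about the
horizontal axis — exactly the machine's kinematics. A test guards the
transform order, since swapping rotate and translate silently produces a
plausible-looking but wrong room.

Modelling choices worth making explicit:

* **Sharp corners.** Box corners are sharp. Real couch tops have rounded
  corners (~2 cm radius on the surveyed couch), so arcs passing a corner
  appear up to ~2 cm closer in the model than in the room. The bias is
  one-sided (conservative).
* **No cone-locking clip.** The clip on the cone-locking mechanism is not
  modelled; it can pass closer to the couch than the cone body and in one
  observed case was the actual collision hazard. Collimator rotation,
  which moves the clip, is likewise out of scope.
* **No patient outline.** The envelope is the frame, not the anatomy.

## Commissioning parameters

The configuration file (`YAML`, JSON accepted) carries the full survey;
`inst/extdata/machine_table1.yaml` is a complete annotated example. The
parameters that require judgement:

* `gia`, `cia`, `gicw`, `cicw` — the readout angles of the overhead,
  no-kick pose and the rotation senses. Internal angles are
  `s · (user − initial)` normalized to (−180, 180], with `s = +1` iff the
  increases-clockwise flag is 1. The mapping between "clockwise" and the
  printed rotation equations is a convention that cannot be derived from
  the equations alone, so the package fixes this rule and `VALIDATION.md`
  prescribes the empirical check (enter a known rotation, watch the
  view, flip the flag if it moves the wrong way) — the same procedure used
  for the shift sign flags.
* `apdir`, `latdir`, `sidir` — planning-system shift sign conventions
  (`vertdir` is accepted as an alias for `sidir`). The 200 mm shift test
  in `VALIDATION.md` pins these; for Brainlab conventions they are
  (−1, 1, −1).
* `chad` — interpreted as the vertical drop from the safety-zone centre
  to the couch-head top surface. The survey value (120 mm) equals the
  posterior frame extent `szp`, consistent with a frame resting on the
  couch top, which is what motivated this reading; a site whose frame
  mounts differently should re-measure accordingly.
* `chse`, `chie`, `cbie` — signed y-extents of the couch boxes relative
  to the safety-zone centre at commissioning; the couch translates
  rigidly with the patient assembly (the frame clamps to the couch head).
* `close_threshold_mm` — default 10: under 1 cm of clearance is treated
  as a collision concern. Exactly 10 mm classifies as clear (the rule is
  strict "< 1 cm").
* Two surveyed values are shipped in both readings rather than silently
  corrected: `sza` was recorded as "155 cm" on an otherwise all-mm sheet
  (both configs use 155 mm; the verbatim config warns on load), and
  `cod = 750` mm exceeds the 670 mm head diameter — the verbatim config
  keeps it, the demo config overrides it to a realistic 75 mm housing.
  The demo override is a package choice, not a surveyed value.
* The couch body length uses `cbie` verbatim (−2240 mm) even though it
  could be shortened for display: the full slab is the conservative
  collision surface.

## Patient placement

Three points connect plan coordinates to the room: isocenter, safety-zone
centre, and a CT-visible reference point (e.g. a rod tip in the mask
base). Commissioning measures all coordinates once on a CT of the empty
mask with the frame in place; at planning time only the reference point
and isocenter are read from the current plan. Per planning axis,

    offset = dir · ((szcomm − refcomm) + (ref_plan − iso_plan)),

mapped lat→x, ap→z, si→y. The arithmetic is linear, so the 200 mm shift
test checks each sign flag independently, and placing the isocenter on
the safety-zone centre cancels everything — a useful identity that the
tests exploit.

## Clearance computation

Every sampled pose scores the six machine×patient pairs
({cone, gantry head} × {couch head, couch body, safety zone}); machine
self-pairs and couch-vs-frame are rigidly attached and never scored.
Each pair is evaluated in two parts:

1. **Intersection** — exact containment of sampled boundary points of
   each solid in the other (plus both centres, catching full
   enclosure). Containment is closed-form per primitive after inverse
   rotation; boundary points count as inside (conservative).
2. **Distance** — every primitive here is convex, and the Euclidean
   projection onto each is exact: clamping for the box, a disk×interval
   product for the cylinder, a 1-D Lagrange bisection for the ellipsoid
   (and elliptic cylinder cross-sections). Alternating projections
   between two disjoint convex bodies converge to the globally closest
   pair from any start, so the reported distance is exact to machine
   precision rather than sampling-limited. A parametric-surface
   minimization with multi-start would also work here; the projection
   route was chosen because convexity gives it a global guarantee, it is
   deterministic and exactly symmetric under lateral mirroring, and it
   needs no tuning. The sampling + `optim`-polish route survives in the
   test suite as the independent oracle the engine is checked against.

If the projection iteration drives the separation below `contact_tol`
(10⁻⁶ mm) the pair is reported as touching (distance 0): a hairline
overlap too thin for the containment sampling to see is still a
collision. Degenerate (non-positive-extent) solids are rejected at
construction. The iteration stops when the distance decreases by less
than 10⁻¹² relative or after 200 iterations; for the flat-face contacts
that dominate this geometry it converges in a handful of steps.

An arc sweep samples `n_points` gantry angles linearly from start to stop
on the readout scale, endpoints included, with **no 0/360 wrapping**:
every surveyed arc is expressible this way and a wrap rule would be a
guess; the complementary sweep is available as `direction = "reverse"`.
The default `n_points = 36` keeps spacing at or under ~5° for a 175°
arc; the shipped fixture plans pin 19 points (~8° on their ~150° arcs) so
the full 20-arc batch stays interactive. Sampling is the one place the
screen is not conservative: a collision strictly between sampled poses
can be missed, so near close calls raise `n_points` (refinement is
monotone — a nested finer sweep can only lower the reported minimum, and
a test asserts this).

Classification: collide if any pose intersects; close if the arc minimum
is below the threshold; clear otherwise. A grazing distance of exactly 0
without the intersecting flag classifies as close — the flag, not the
number, signals collision.

## What the fixtures emulate — and what they do not

`machine_table1.yaml` is a real single-machine survey; `machine_demo.yaml`
differs only in the cone diameter. The three demo plans transcribe the
published arc geometries of three SRS patients (8 + 5 + 7 arcs), but the
published cases do not include isocenter or reference coordinates, so the
shipped values are **synthetic**, chosen once with anatomically sensible
signs (right orbital gyrus: frame centre left/superior/posterior of the
isocenter by (20, 40, −30) mm; analogous reasoning for the two cerebellar
cases) and such that the first plan demonstrates both colliding and
clearing arcs. Consequently the fixture classifications are
demonstrations of the engine, **not** reproductions of the published
software-vs-room comparison: that comparison requires the unpublished
isocenters and a physical room. Passing tests show the geometry engine is
right, the conventions are applied as documented, and the pipeline is
deterministic — they cannot show that a particular clinic's survey or
sign flags are correct, which is exactly what the in-room commissioning
checks in `VALIDATION.md` exist for.

The random-pair generator used for oracle testing draws primitive kinds,
extents in [50, 700] mm, centres in ±400 mm and a random single-axis
rotation: sized to straddle treatment-room scales and tuned (once, at
generator design time) so that of 100 seeded pairs at least 20 intersect
and at least 20 are disjoint.

## Numerical choices and test scale

* Mesh resolution: rendering uses 64 azimuthal × 33 axial samples for
  curved solids and sharp 2×2 faces for boxes; collision sampling uses
  coarser meshes (24 azimuthal; 8 per box face edge) because sampling
  only seeds the intersection test — the distance itself is
  projection-exact. A test asserts the shipped fixture classifications
  are unchanged at double resolution.
* Bisection for ellipse/ellipsoid projections runs 100 halvings from a
  bracketing interval: ~10⁻³⁰ relative, deterministic, and exactly
  mirror-symmetric because it operates on squared coordinates.
* Ties: `which.min` takes the first minimal sample (stable ordering), so
  reports are byte-reproducible; the arc minimum itself is
  tie-independent.
* Angle normalization to (−180, 180] prevents arc aliasing; at the
  commissioned initial angles the internal rotations are exactly 0 and
  the scene equals its unrotated construction bit-for-bit (cos 0 and
  sin 0 are exact).
* Test problem sizes: the oracle cross-check runs 100 seeded pairs at
  24×24 samples per patch with quasi-Newton polish; sweeps in tests use
  3–19 poses per arc. These sizes were chosen to probe every code path
  while keeping the default suite in the tens of seconds.

## Known limitations

Pose sampling (no swept-volume certificate between samples); sharp
corners and the frame envelope both over-predict; no penetration depth
(a collision is a boolean plus zero distance — depth adds nothing to the
go/no-go decision); one couch model per configuration; no collimator
angle, gantry sag, or couch translation during delivery; no DICOM-RT
ingestion (plan files are deliberately minimal JSON).
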