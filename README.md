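# conearc

Desk-side pre-screening of **stereotactic cone collisions** for
linac-based intracranial SRS arc plans.

Cone-based stereotactic radiosurgery delivers multiple non-coplanar arcs,
and the cone — the machine part closest to the patient — can collide with
the treatment couch or the patient's head when large couch kicks are
combined with low gantry angles. Discovering this only during in-room
simulation forces replanning; avoiding it by restricting couch angles
degrades dose falloff. `conearc` lets planners, physicists and physicians
screen a beam geometry for collisions at planning time. It is a
conservative geometric pre-screen and **never replaces the in-room
collision check**.

## The model

All geometry lives in IEC 61217 fixed coordinates for a head-first supine
patient (x = patient left, y = superior, z = anterior; mm; the isocenter
is the origin). Five room components are modelled as convex primitives
built from unit solids by the fixed chain **scale → translate → rotate**:

| component    | primitive | placement (from the commissioning survey)           |
|--------------|-----------|------------------------------------------------------|
| cone         | cylinder  | diameter `COD`, spanning z ∈ [`CAD`, `HAD`]          |
| gantry head  | cylinder  | diameter `HOD`, spanning z ∈ [`HAD`, `HAD` + `HT`]   |
| couch head   | box       | `CHW` × (`CHSE` − `CHIE`) × `CHT`, top `CHAD` below the frame centre |
| couch body   | box       | `CBW` wide, abutting the couch head inferiorly        |
| safety zone  | box or ellipsoid | the localization frame that fully contains the head: extents `SZR`+`SZL`, `SZS`+`SZI`, `SZA`+`SZP` |

Scaling and translation apply componentwise
(`x_scaled = C_x·x_unit + Δ_x`); gantry-mounted solids then rotate about
y (`x' = x cos θ − z sin θ`, `z' = x sin θ + z cos θ`) and couch-mounted
solids about z. Machine readout angles map to these internal rotations
through the commissioned initial angles (`GIA`, `CIA`) and
increases-clockwise flags (`GICW`, `CICW`).

The patient assembly is placed by three points: the treatment isocenter,
the safety-zone centre, and a CT-visible **reference point** whose
commissioning-time relation to the frame is measured once. Per planning
axis `a ∈ {lat, ap, si}`,

```
offset_a = dir_a · ((szcomm_a − refcomm_a) + (ref_plan_a − iso_plan_a))
```

with the planning-system sign flags `dir` (`LATDIR`, `APDIR`, `SIDIR`),
mapped to room axes lat→x, ap→z, si→y.

Each arc (fixed couch angle, gantry start → stop) is sampled at `n`
gantry angles; at each pose all six machine×patient pairs are scored by
their exact minimum distance (alternating convex projections, so disjoint
distances are exact to machine precision) and intersection is tested by
exact point containment. The arc is classified **clear** (minimum
clearance ≥ 10 mm), **close** (< 10 mm — under 1 cm of clearance is a
collision concern), or **collide**.

## Worked example

The package ships a demonstration machine survey (`machine_demo.yaml`)
and three demo plans whose arc geometries are transcribed from published
SRS cases (isocenters are synthetic — the cases do not publish them):

```r
library(conearc)
cfg <- default_machine_config("demo")
pf  <- demo_plan("t2")                    # 8 arcs, right orbital gyrus case
res <- run_batch(cfg, pf, "report/", quiet = TRUE)
res$table
```

```
  beam couch_angle gantry_start gantry_stop min_clearance_mm argmin_gantry    limiting_pair classification
1    1         180          200         350            21.86        316.67  cone:couch_head          clear
2    2         255          160          10             0.00         60.00  cone:couch_head        collide
3    3         205           10         160            27.41         43.33  cone:couch_head          clear
4    4         130          200         350             0.00        233.33 cone:safety_zone        collide
5    5         255          165          45             0.00         65.00  cone:couch_head        collide
6    6         195           55         165            58.79         55.00  cone:couch_head          clear
7    7         165          195         315            10.70        315.00  cone:couch_head          clear
8    8         105          315         195             0.00        315.00  cone:couch_head        collide
```

Beam 3 keeps 27.4 mm between the cone and the couch head at its worst
pose (gantry 43.3°): clear. Beams with large couch kicks (255°, 130°,
105°) drive the cone into the kicked couch or the frame: collide. The
batch exit status is 3 (collide) / 2 (close) / 0 (all clear), for
pipeline use; `report/report.csv` and `report.json` hold one row per arc,
and `--render` adds a swept-arc PNG per beam.

From a shell:

```sh
conearc check --config machine.yaml --plan plan.json --out report/ --render
conearc interactive --config machine.yaml
conearc validate-config machine.yaml
```

(`conearc` is installed under `exec/` in the package library.) The
interactive mode mirrors the original guided workflow: reference point →
isocenter + envelope shape + number of angles → beam geometry → view,
then a menu to change any one group and re-run.

Room views come from `render_scene()` / `render_arc()`; commissioning
files are plain YAML (see `inst/extdata/machine_table1.yaml` for the
fully annotated survey).

## Limitations

Sharp-cornered boxes over-predict collisions near rounded couch corners
(by about the corner radius); the frame-sized safety zone is conservative
for any actual head; the cone-locking clip is not modelled; arcs are
screened at sampled poses, not as swept volumes — increase `n_points`
near close calls. See the methods vignette
(`vignettes/cone-collision-screening.Rmd`) for the full discussion.
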