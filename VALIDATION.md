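# Commissioning validation checklist

`conearc` is a pre-screen: before clinical use, the configured model must
be validated against the actual treatment room, and the in-room collision
check remains mandatory for every patient. The software test suite proves
the geometry engine; only the checks below prove *your survey and sign
conventions*.

## 1. Sign-convention shift test (planning-system flags)

For each axis in turn, enter a large isocenter shift (e.g. 200 mm) in the
planning-system coordinates and confirm in the rendered view that the
safety zone moves the correct way in the room (a positive room shift is
patient-left / superior / anterior). If an axis moves the wrong way, flip
the corresponding flag (`latdir`, `sidir`, `apdir`) in the config. For
Brainlab conventions the result is `latdir = 1`, `apdir = -1`,
`sidir = -1`.

## 2. Rotation-sense test (gantry and couch flags)

From the overhead pose (`gia`, `cia`), command a modest gantry rotation
on the machine (e.g. +10 on the readout) and render the same angles.
If the rendered gantry swings to the opposite side of the room, flip
`gicw`. Repeat for the couch with `cicw`. This pins the
increases-clockwise convention to your room; it cannot be inferred from
the survey alone.

## 3. Couch-corner collision replication

With the gantry rotating, translate the couch until the cone contacts
each corner of the couch top in the room (machine in service/careful
manual mode, no patient). Replicate each contact couch position in the
software and confirm it reports collide or close at the matching pose.
Repeat for the corners of the localization frame mounted on the couch.
Expect the software to report contact up to ~2 cm *earlier* than the room
near rounded couch corners (the model's corners are sharp).

## 4. End-to-end patient replication

Take a past clinical plan, set its reference point and isocenter in the
software, and step through every arc on the linac and in the rendered
view, confirming coincident motion of gantry, cone, couch and frame, and
that each isocenter shift is reproduced. Record each arc as
clear / close (< 1 cm) / collide in both columns and investigate any
disagreement beyond the rounded-corner allowance.

## 5. Re-validation triggers

Repeat this checklist after any change of couch top, localization frame,
cone mounting hardware, planning system version or its coordinate
conventions, and after any machine geometry service.
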