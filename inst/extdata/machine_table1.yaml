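# Verbatim machine commissioning survey (lengths in mm unless noted,
# angles in degrees).  Two entries are kept exactly as surveyed although
# they look suspect: sza was recorded as "155 cm" on an otherwise all-mm
# sheet (used here as 155 in config units), and cod = 750 mm exceeds the
# gantry-head diameter.  See machine_demo.yaml for the plausible variant.
szs: 165          # safety zone extent, superior of its centre
szi: 165          # inferior
sza: 155          # anterior (surveyed as "155 cm"; see note above)
szp: 120          # posterior
szr: 115          # patient right
szl: 115          # patient left
cod: 750          # cone outer diameter (surveyed value; implausible)
cht: 20           # couch head thickness
chad: 120         # couch head axis distance (safety-zone centre to couch top)
cad: 256          # cone axis distance (isocenter to cone distal face)
chw: 282          # couch head width
chse: 200         # couch head superior extent (signed, along y)
chie: -113        # couch head inferior extent
cbie: -2240       # couch body inferior extent
cbw: 530          # couch body width
hod: 670          # gantry head outer diameter
ht: 670           # gantry head thickness
had: 437          # head axis distance (isocenter to head face)
gia: 180          # gantry initial angle (overhead pose)
gicw: 0           # gantry readout increases clockwise? (0 = no)
cia: 180          # couch initial angle (no kick)
cicw: 1           # couch readout increases clockwise? (1 = yes)
szlatcomm: 2      # planning-system coords of safety-zone centre at commissioning
szapcomm: 1.8
szsicomm: 0.8
reflatcomm: 103.1 # planning-system coords of reference point at commissioning
refapcomm: 4
refsicomm: 23.3
apdir: -1         # planning-system shift sign conventions (Brainlab)
latdir: 1
sidir: -1
szcolor: [1.0, 0.0, 0.0]       # safety zone: red
chcolor: [0.3, 0.3, 0.3]       # couch: dark gray
ccolor: [0.75, 0.75, 0.75]     # cone: light gray
hcolor: [0.72, 0.62, 0.08]     # gantry head: dark yellow
label_ap: "Y"                  # Brainlab axis labels
label_lat: "X"
label_si: "Z"
close_threshold_mm: 10
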