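# Reference vessel constants (ABI = 1 baseline). Overridable via the
# `constants` field of a run configuration; values in the units noted.
capillary:
  diameter: 0.007            # mm
  length: 0.0007             # m
  wall_thickness: 0.0005     # mm
  viscosity: 0.0012          # Pa.s
  density: 1060              # kg/m^3
  reference_pressure: 25     # mmHg
artery:
  # literature constants taken as given, never recomputed from geometry
  arterial_pressure: 120     # mmHg (ankle systolic at ABI = 1)
  arterial_flow: 5.30e-4     # m^3/s
  arterial_resistance: 3.02e7  # Pa.s/m^3
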