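# Example scene/pipeline configuration for `canopy3d run --config ...`.
# All fields are optional; omitted ones fall back to the documented
# defaults (a ~1.8 m canopy of 30 curved leaves in a ~0.34 m^3 region,
# scanned from 3 stations 120 degrees apart at 5 m).
seed: 1
n_leaves: 30
height: 1.8
footprint: [0.435, 0.435]
layer_thickness: 0.2
scanner:
  n_stations: 3
  azimuths_deg: [0.0, 120.0, 240.0]
  range: 5.0
  station_height: 1.5
  zenith_span_deg: [81.0, 107.0]
  range_noise_sd: 0.001
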