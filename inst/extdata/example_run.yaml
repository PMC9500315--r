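# Shipped example: instrumented C2-T2 phantom with the reference per-region
# densities, all four motion load cases, and the safety evaluation.
# Units: mm / N / MPa / N*mm.
phantom:
  mesh_size: 3.5
instrument:
  spacer_heights: [8, 8, 7]
  screw_diameter: 4.0
  screw_length: 15.0
  plate_length: 55
  plate_span: [C2, C3, C4, C5]
  plate_standoff: 0
law_mode: as_used
load:
  body_mass_kg: 39.97
  head_fraction: 0.0783
  g: 9.81
  strengths:
    flexion: 418
    extension: 683
    lateral_flexion: 542
    rotation: 208
  fix_level: T2
  motions: [all]
solver:
  rtol: 1.0e-8
  max_outer: 50
  penalty_factor: 50
  penetration_tol: 1.0e-3
  validate: true
output:
  write_fields: false
seed: 1
log_level: info
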