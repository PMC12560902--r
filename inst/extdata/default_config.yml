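# Default tag-burden pipeline configuration.
# All quantities SI: lengths m, speeds m/s, masses kg, density kg/m^3,
# dynamic viscosity Pa.s. Units are fixed by this contract; none are
# inferred from the file.
fluid:
  density: 1025          # seawater at 20 C
  dynamic_viscosity: 0.00109
geometry:
  fork_length: 2.95      # adult lamnid body
  # frontal_area: 0.12   # override; otherwise area_coefficient * L^2
  area_coefficient: 0.01378914
mass_model:
  anchor_length: 1       # m
  anchor_mass: 17        # kg
  exponent: 3            # isometric
# drag_table: path/to/table.csv   # omit to use the packaged sweep
scenarios:
  burst_speeds: [3.6, 5.0, 7.8, 9.1]
  burst_fractions: {from: 0.0, to: 0.20, by: 0.01}
  glide_fraction: 0.07
  cruise_speed: 1.0
  tagged_configs: [archival_body, fin_mount]
report:
  sizes: [1.0, 1.5, 2.0, 2.5, 2.95]
  speeds: [0.5, 1.0, 1.5, 2.0, 3.6, 5.0, 7.8, 9.1]
  configs: [archival_body, fin_mount]
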