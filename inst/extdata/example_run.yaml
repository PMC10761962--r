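# Example configuration: 5.6 mm wavelength stripes on a 11.2 mm periodic
# unit cell, evaluated over 40 h (desk-scale version of the stripe sweep).
grid:
  extent: 11.2
  spacing: 0.1
  bc: periodic
pattern:
  generator: periodic_lines
  lambda: 5.6
  duty: 0.25
  I0: 1.13
solver:
  t_end: 40
  out_times: [0, 10, 20, 30, 40]
seed: 1
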