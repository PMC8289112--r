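# Example experiment: one ambient density, four food footprints spanning the
# too-narrow / optimal / too-wide / no-food regimes of group formation.
preset: symmetric
grid:
  L: 21.428571428571427   # 3/0.14
  n: 256
solver:
  t_end: 12.5
  rtol: 1.0e-6
  atol: 1.0e-9
sweep:
  rho_amb: [1.2]
  omega: [0.0, 7.5, 10.0, 12.5]
  F_M: [1.5]
  replicates: [1]
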