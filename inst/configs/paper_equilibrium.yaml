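# Paper-scale equilibrium geometry: liquid-vapor slab with adsorbed block
# copolymers. LONG-RUNNING: ~2e5 particles-steps budget far beyond desk scale
# (days on one CPU); provided for completeness, desk presets cover testing.
stage: md-equilibrate
seed: 1
output: out/paper-equilibrium
system:
  mode: lv
  rho: 0.8
  T: 0.723
  box: [50.56, 50.56, 92.96]   # bulk phase equilibrated at Lz 46.77, then extended
  steps_bulk: 100000
  steps_slab: 200000
copolymers:
  architecture: H30T10          # or T5H10T5 with count 400
  count: 150
  bond: harmonic
  steps_after_insert: 300000
sampling:
  steps: 250000
  every: 50
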