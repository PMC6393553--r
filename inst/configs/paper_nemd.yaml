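# Paper-scale NEMD geometry: symmetric W|O|W liquid-liquid sandwich with
# H_n T_n diblocks under Lees-Edwards shear. LONG-RUNNING; desk presets
# (desk-hn5/10/15) are the tested scaled-down analogues.
stage: nemd-shear
seed: 1
output: out/paper-nemd
system:
  mode: ll
  rho: 0.7
  T: 1.0
  box: [50.56, 50.56, 92.96]
  steps_equil: 100000
copolymers:
  architecture: H10T10          # n = 5, 10, 15
  count: 150
  bond: fene
  steps_after_insert: 150000
shear:
  rate: 0.01
  steps: 500000                 # run-in to steady state
sampling:
  steps: 250000
  every: 50
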