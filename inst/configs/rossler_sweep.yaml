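# Coupled-oscillator case study: error sweep over the sampling budget for
# the karate-club simplicial complex with fourth-order derivatives.
schema: hordyn/experiment/v1
model:
  name: rossler
structure:
  fixture: karate
  delta: 1.0
sampling:
  t_max: 60
  transient: 20
derivative: 4
solver:
  name: nnls
sweep:
  ratios: [2.0, 3.17, 5.02, 7.96]
  replicates: 1
seed: 1
out_dir: rossler_sweep
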