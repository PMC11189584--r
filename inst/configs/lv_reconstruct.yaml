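# Microbial-ecosystem case study: simulate the 7-species generalized
# Lotka-Volterra hypergraph and reconstruct it from exact derivatives.
schema: hordyn/experiment/v1
model:
  name: lv
structure:
  fixture: lv
  weight_scale: 0.01
sampling:
  t_max: 20
  M: 200
derivative: exact
solver:
  name: ols
seed: 1
out_dir: lv_run
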