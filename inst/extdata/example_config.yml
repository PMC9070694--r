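# run configuration consumed by read_run_config()
model: saxs_table1
seed: 11
data: curve.tsv
output_dir: results
parameters:
  I0:     {init: 1.0}
  Ib:     {init: 1.0e-5}
  R:      {init: 500}
  sigR:   {init: 20}
  sigq:   {fixed: 0}
  sigma2: {init: 0.01}
sampler:
  n_iterations: 2000
  n_burn_in: 500
  step_size: 0.05
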