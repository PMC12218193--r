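# Synthetic two-wave scenario: the red group's opinion covariance contracts
# between waves while group means (and the blue group) stay put.
seed: 20260920
scenario:
  truncation: resample
  waves:
    t1:
      - {label: red,  size: 400, mean: [0.75, 0.75], cov: [0.004, 0.004]}
      - {label: blue, size: 400, mean: [0.35, 0.40], cov: [[0.030, 0.012], [0.012, 0.020]]}
    t2:
      - {label: red,  size: 400, mean: [0.75, 0.75], cov: [0.001, 0.001]}
      - {label: blue, size: 400, mean: [0.35, 0.40], cov: [[0.030, 0.012], [0.012, 0.020]]}
lens:
  mode: instantaneous
  ridge_epsilon: 1.0e-6
  min_group_size: 3
baseline: t1
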