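{
  "r": 4,
  "a": 0.1,
  "b": 1,
  "b_tilde": 0.01,
  "a_logistic": 0,
  "K": 100,
  "x0": 100,
  "y0": 0,
  "mode": "deterministic",
  "sigma": [100, 0],
  "t_points": [0.5, 0.7, 0.9],
  "n_paths": 10000,
  "dt": 0.001,
  "seed": 1
}
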