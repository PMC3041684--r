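{
  "seed": 2026,
  "spec": {
    "n_tips": 10,
    "birth": 0.5,
    "age": 6.9,
    "alpha": 0.2,
    "k": 3,
    "records_mean": 12
  },
  "node_states": [2, 1, 2, 1, 0, 2, 1, 0, 2, 0, 1, 1, 1, 1, 0, 1, 2, 0, 2]
}
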