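{
  "dataset_composition": {
    "n_donor": 157949,
    "n_acceptor": 157949,
    "n_generic": 496290
  },
  "flanking_lengths": [130, 200, 500, 1000],
  "reported_window_lengths": [261, 401, 1001, 2001],
  "split_fractions": [0.8, 0.1, 0.1],
  "reported_averages": {
    "human": {"accuracy": 99.04, "top_k": 81.25, "top_half": 97.0, "fp": 0.11},
    "other": {"accuracy": 95.45, "top_k": 57.80, "top_half": 89.70, "fp": 0.25}
  }
}
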