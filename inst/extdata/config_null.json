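{
  "seed": 202,
  "simulate": {
    "n_blocks": 3,
    "artifact_rate": 0.15,
    "effects": []
  },
  "spectral": {"n_perm": 200},
  "classify": {"n_perm": 200}
}
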