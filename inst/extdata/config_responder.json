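{
  "seed": 103,
  "simulate": {
    "n_blocks": 3,
    "artifact_rate": 0.15,
    "effects": [
      {
        "condition": "left",
        "channel_side": "ipsilateral",
        "band": [25, 30],
        "depth": 1.0,
        "latency": 1,
        "duration": 1,
        "ramp": 0.25
      }
    ]
  },
  "spectral": {"n_perm": 200},
  "classify": {"n_perm": 200}
}
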