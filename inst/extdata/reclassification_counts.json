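{
  "comment": "Printed paired 3x3 reclassification counts (rows = existing-model band, cols = updated-model band, order low/intermediate/high), split by outcome.",
  "events": [[30, 26, 0], [27, 43, 20], [0, 28, 31]],
  "nonevents": [[623, 74, 0], [243, 322, 63], [0, 189, 66]]
}
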