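- id: chain3
  t_end: 120.0
  tracer:
    A:
      mask:
      - 1
      - 0
      fraction:
      - 0.5
      - 0.5

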