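- id: symmetric_krebs_stub
  t_end: 120.0
  tracer:
    X:
      mask:
      - 1
      fraction:
      - 1.0

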