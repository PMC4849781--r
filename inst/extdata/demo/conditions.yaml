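- id: A1
  t_end: 120.0
  initial:
    eGlc: 20.0
    eFru: 3.0
  tracer:
    eGlc:
      mask:
      - 3
      - 0
      fraction:
      - 0.5
      - 0.5
- id: A2
  t_end: 120.0
  initial:
    eGlc: 20.0
    eFru: 3.0
  tracer:
    eFru:
      mask:
      - 63
      - 0
      fraction:
      - 0.5
      - 0.5
- id: B
  t_end: 120.0
  initial:
    eGlc: 20.0
    eFru: 20.0
  tracer:
    eGlc:
      mask:
      - 3
      - 0
      fraction:
      - 0.5
      - 0.5

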