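compartments:
- id: c
  name: cell
  volume: '1'
metabolites:
- compartment: c
  constant: no
  id: A
  initial_concentration: '1.5'
  labelable: yes
  n_carbons: 3
  name: A
- compartment: c
  constant: no
  id: B
  initial_concentration: '1.5'
  labelable: yes
  n_carbons: 3
  name: B
name: loop_exchange
ncell: '1'
reactions:
- id: r1
  invisible: no
  law:
    template: massAction
    params:
      k: r1.k
      kr: r1.kr
  name: r1
  products:
    B: 1.0
  reversible: yes
  substrates:
    A: 1.0
- id: x1
  invisible: yes
  law:
    template: exchange
    params:
      k: x1.k
  name: x1
  products:
    B: 1.0
  reversible: no
  substrates:
    A: 1.0
symmetric_metabolites: []

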