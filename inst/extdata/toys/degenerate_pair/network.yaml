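compartments:
- id: c
  name: cell
  volume: '1'
metabolites:
- compartment: c
  constant: yes
  id: A
  initial_concentration: '1'
  labelable: yes
  n_carbons: 3
  name: A
- compartment: c
  constant: no
  id: B
  initial_concentration: '0.2'
  labelable: yes
  n_carbons: 3
  name: B
- compartment: c
  constant: no
  id: C
  initial_concentration: '0'
  labelable: yes
  n_carbons: 3
  name: C
name: degenerate_pair
ncell: '1'
reactions:
- id: r1
  invisible: no
  law:
    template: massAction
    params:
      k: r1.k
  name: r1
  products:
    B: 1.0
  reversible: no
  substrates:
    A: 1.0
- id: r2
  invisible: no
  law:
    template: massAction
    params:
      k: r2.k
  name: r2
  products:
    C: 1.0
  reversible: no
  substrates:
    B: 1.0
symmetric_metabolites: []

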