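compartments:
- id: c
  name: cell
  volume: '1'
metabolites:
- compartment: c
  constant: no
  id: M
  initial_concentration: '2'
  labelable: yes
  n_carbons: 4
  name: M
- compartment: c
  constant: no
  id: S
  initial_concentration: '2'
  labelable: yes
  n_carbons: 4
  name: S
- compartment: c
  constant: no
  id: waste
  initial_concentration: '0'
  labelable: no
  n_carbons: 4
  name: waste
- compartment: c
  constant: yes
  id: X
  initial_concentration: '10'
  labelable: yes
  n_carbons: 4
  name: X
name: symmetric_krebs_stub
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
    S: 1.0
  reversible: no
  substrates:
    X: 1.0
- id: r2
  invisible: no
  law:
    template: massAction
    params:
      k: r2.k
  name: r2
  products:
    M: 1.0
  reversible: no
  substrates:
    S: 1.0
- id: r3
  invisible: no
  law:
    template: massAction
    params:
      k: r3.k
  name: r3
  products:
    waste: 1.0
  reversible: no
  substrates:
    M: 1.0
symmetric_metabolites:
- S

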