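# example run configuration for the command-line interface
network: inst/extdata/demo/network.yaml
atom_maps: inst/extdata/demo/atom_maps.tsv
params: inst/extdata/demo/parameters.tsv
conditions: inst/extdata/demo/conditions.yaml
measurements: inst/extdata/demo/synthetic_measurements.tsv
groups: inst/extdata/demo/groups.tsv
condition: B
out_dir: demo_run
seed: 1
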