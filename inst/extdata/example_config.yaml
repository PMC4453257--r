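# Example run configuration: excitatory-homeostasis circuit, default grid.
circuit:
  mode: excitatory
grid:
  min: -4
  max: 4
  step: 0.01
training:
  intensities: [-1, 0, 1]
  shock: true
seed: 1
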