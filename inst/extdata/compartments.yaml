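compartments:
- id: Nn
  description: neuron nucleus
  volume: 0.033
- id: Nc
  description: neuron cytosol
  volume: 0.33
- id: Nm
  description: neuron mitochondrion
  volume: 0.0855
- id: An
  description: astrocyte nucleus
  volume: 0.019
- id: Ac
  description: astrocyte cytosol
  volume: 0.19
- id: Am
  description: astrocyte mitochondrion
  volume: 0.0475
- id: e
  description: extracellular space
  volume: 0.2
- id: b
  description: capillary blood
  volume: 0.095
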