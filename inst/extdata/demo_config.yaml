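# Demo pipeline configuration: all stages, small synthetic inputs.
stages: [simulate, kymo, contract, helix, pixstats, dynamics]
seed: 7
params:
  geometry:
    contraction_amplitude: 0.2
  localizations:
    n_points: 20000
    precision_nm: 15
  nb:
    n_molecules: 50
    brightness: 4
    n_frames: 300
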