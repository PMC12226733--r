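# Demo pipeline configuration: synthetic wildtype-like study conditions.
seed: 1
temperatureK: 294
spmUM: 30
noiseSD: 0.02
normalizationMode: to_max
blockerTruth:
  gmax: 1
  g: 10
  h: -18.5
  L: 1.4
  k: 36.5
  vrev: 0
dose:
  ec50: 0.11
  hillSlope: 1.5
  unit: mM
  ligand: glycine
recovery:
  tau: 184
  amplitude: -0.9
stages: [simulate, iv, blocker, dose, recovery, sites]
verbosity: 1
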