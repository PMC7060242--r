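# Example pipeline configuration for `pathscore run` / runPipeline().
# A small two-arm experiment: wildtype vs a known activating variant.
sim:
  params:
    fovSize: 256
    meanCells: 220
    sdCells: 48
  plateSize: 8
  design:
    - gene: KRAS
      variant: WT
      annotation_class: WT
      alpha: 0.05
      n_wells: 24
    - gene: KRAS
      variant: G12D
      annotation_class: activating
      alpha: 0.9
      n_wells: 24
split:
  fractions: [0.6, 0.2, 0.2]
model:
  scales: [256, 128]
  patch: 128
train:
  batchSize: 16
  learningRate: 1.0e-4
  maxEpochs: 40
  patience: 15
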