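# Paper-scale profile: 96^3 detector patches, 48^3 FPR cubes, 100-epoch SGD
# schedules, tenfold cross-validation over the 888 LUNA16 scans. Requires the
# external LUNA16 download and GPU-scale compute; the package's built-in desk
# profile is the tested default.
detector:
  input_size: 96
  widths: [24, 32, 64, 64, 64]
  blocks_per_stage: 2
  decoder_blocks: 3
  decoder_channels: 64
  anchors: [5, 10, 20]
  k_att: 7
fpr:
  input_size: 48
  widths: [16, 32, 64]
  stem_width: 16
  dropout: 0.5
  k_att: 7
train:
  detector:
    epochs: 100
    batch_size: 16
    lr0: 0.01
    milestones: [50]
    lr_values: [0.001]
  fpr:
    epochs: 100
    batch_size: 128
    lr0: 0.01
    milestones: [40, 80]
    lr_values: [0.001, 0.0001]
  momentum: 0.9
  weight_decay: 0.0001
  folds: 10
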