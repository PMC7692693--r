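# Default configuration for the voxpath command-line tools.
# Synthetic-cohort parameter ranges are uniform per class; training
# hyperparameters are per model family.

synth:
  duration_s: 4.0
  sample_rate_hz: 50000
  normal:
    f0_hz: [100, 140]
    jitter_frac: [0.002, 0.005]
    shimmer_frac: [0.01, 0.04]
    hnr_db: [22, 32]
  pathological:
    f0_hz: [90, 150]
    jitter_frac: [0.02, 0.04]
    shimmer_frac: [0.06, 0.12]
    hnr_db: [2, 10]

preprocess:
  mfcc_rate_hz: 16000
  stft_rate_hz: 4000
  cnn1d_rate_hz: 22050
  cnn1d_pad_len: 98304
  crops_per_image: 10

train:
  svm:
    kernel: radial
    cost: 1.0
  xgb:
    nrounds: 200
    max_depth: 4
    eta: 0.1
  lgbm:
    nrounds: 200
    max_leaves: 16
    eta: 0.1
  ann:
    epochs: 60
    batch_size: 8
    lr: 0.001
  cnn1d:
    epochs: 16
    batch_size: 8
    lr: 0.001
  cnn2d:
    epochs: 12
    batch_size: 16
    lr: 0.001
    dropout: 0.3
    aggregation: mean

evaluate:
  folds: 5
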