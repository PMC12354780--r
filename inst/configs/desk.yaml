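# Desk-scale profile: 64 x 64 phantoms, small 2-level network, short
# training. Runs end to end on one CPU in a few minutes.
seed: 1
out_dir: gravseg_run
forge:
  n: 200
  height: 64
  width: 64
prep:
  bilateral: true
  sigma_s: 1.0
  sigma_r: 0.15
  blur_sigma: 0
  split: [0.7, 0.2, 0.1]
model:
  input_size: 64
  levels: 2
  base_filters: 8
  inception_modules: 1
  bottleneck_ratio: 0.5
  dropout: 0.3
  use_residual: true
  use_pyramid_pool: false
  use_stamps: true
  out_channels: 1
train:
  learning_rate: 0.001
  batch_size: 8
  epochs: 12
  early_stop_patience: 15
loss:
  w_focal: 0.27
  w_dice: 0.69
  w_hausdorff: 0.04
  alpha: 0.25
  gamma: 2
go:
  population: 15
  iterations: 25
  lambda: 0.02
classifier:
  learning_rate: 0.05
  max_depth: 6
  num_leaves: 40
  feature_fraction: 0.9
  bagging_fraction: 0.8
  n_rounds: 60
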