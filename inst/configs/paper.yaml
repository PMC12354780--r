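# Full-scale profile: 512 x 512 inputs downsampled to a 32 x 32
# bottleneck over 4 levels, batch 32, 100 epochs, and the published
# stage-2 booster settings. This scale expects GPU-class resources and
# real imaging data behind the same manifest format; it is not exercised
# by the test suite.
seed: 1
out_dir: gravseg_full_run
forge:
  n: 2000
  height: 512
  width: 512
prep:
  bilateral: true
  sigma_s: 2.0
  sigma_r: 0.1
  blur_sigma: 1.0
  split: [0.7, 0.2, 0.1]
model:
  input_size: 512
  levels: 4
  base_filters: 32
  inception_modules: 3
  bottleneck_ratio: 0.5
  dropout: 0.3
  use_residual: true
  use_pyramid_pool: true
  use_stamps: true
  out_channels: 2
train:
  learning_rate: 0.001
  batch_size: 32
  epochs: 100
  early_stop_patience: 15
loss:
  w_focal: 0.27
  w_dice: 0.69
  w_hausdorff: 0.04
  alpha: 0.25
  gamma: 2
go:
  population: 25
  iterations: 100
  lambda: 0.02
classifier:
  learning_rate: 0.05
  max_depth: 6
  num_leaves: 40
  feature_fraction: 0.9
  bagging_fraction: 0.8
  n_rounds: 200
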