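# Example run configuration for `read_run_config()` / scripts/orchardvit.
model:
  num_classes: 3
  image_size: 32
  patch_size: 8
  hidden_size: 32
  num_layers: 2
  num_heads: 2
  mlp_size: 64
  head_widths: 32
  dropout_rate: 0.0
  boundary_policy: resize
loss:
  gamma: 2
  dv: 1
train:
  learning_rate: 0.001
  batch_size: 32
  epochs: 30
  loss_kind: mfce
  seed: 1
  split: [0.8, 0.1, 0.1]
data:
  dir: orchard-demo
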