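# Example synthetic scene: mixed hexagonal platelets and rods over an
# uneven background. Usable with read_scene_config() or the CLI:
#   nanoshapes simulate --config example_scene.yaml --out-image scene.tif \
#       --out-truth truth.csv
image_size: [512, 512]
nm_per_px: 1.0
polarity: dark_particles
shape_mix:
- family: regular_polygon
  fraction: 0.5
  size_nm: [33.6, 2.0]
  aspect_ratio: [1.0, 0.0]
  n_sides: 6
- family: rod
  fraction: 0.5
  size_nm: [38.1, 1.7]
  aspect_ratio: [1.37, 0.08]
n_particles: 30
aggregate_fraction: 0.0
background_model: linear_gradient
background_level: 160.0
gradient_amplitude: 0.3
contrast: 70.0
noise_sigma: 3.5
seed: 1
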