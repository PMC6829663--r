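# Demo configuration for the tirfgranule pipeline.
# Simulates a small docking movie, then any stage can be run on it, e.g.
#   Rscript inst/cli/tirfgranule.R simulate inst/extdata/demo_config.yaml --outdir demo
#   Rscript inst/cli/tirfgranule.R dock     inst/extdata/demo_config.yaml --outdir demo
outdir: demo
seed: 11
pixel_size: 100        # nm per pixel
frame_interval: 1      # seconds

simulate:
  image_shape: [96, 96]
  n_frames: 120
  background_level: 100
  snr: 10
  psf_sigma: 1.3
  arrival_rate: 0.15
  p_dock: 0.5

detect:
  min_separation: 3
  smoothing_sigma: 1
  # prominence: null -> adaptive 5 x robust background sd

dock:
  link_radius: 3
  max_gap: 1
  confine_radius: 1.5  # px (150 nm)
  t_min: 2             # s, minimum confined residence for an approach
  t_dock: 25           # s, docked threshold
  t_survival: 40       # s, stable-docking horizon

fuse:
  drop_fraction: 0.5
  loss_max: 2
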