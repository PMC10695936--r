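# Multi-seed white-box audit of the rare-z two-moons task.
# Run: Rscript inst/cli/ufm.R multiseed --config inst/extdata/two-moons-audit.yaml --out out/
experiment: multiseed
n_seeds: 10
seed: 0
data:
  generator: two_moons
  n: 1000
  noise_xy: 0.1
  z_mode: zeros
  carrier_z: 1
  carrier_label: 1
train:
  arch: MLP-2
  learning_rate: 0.001
  batch_size: 128
  max_epochs: 100
  patience: 5
audit:
  setting: white
  pool: test
  alpha: 0.05
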