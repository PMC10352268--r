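# Default pipeline configuration: the full seven-agent study at SNR 50.
seed: 1
output: lfrelax_out
agents: default          # or a list of panel names, e.g. [B, D, Gd-BOPTA]
channels: [r1, r2]
fields: [0.064, 3]
phantom:
  grid: [32, 32, 1]
  radius: 4              # tube radius in voxels
  background_r1: 0.35    # agarose 1/T1', 1/s
  background_r2: 1.5     # agarose 1/T2', 1/s
noise:
  image_sigma: 0.02      # magnitude noise as fraction of S0 (SNR 50)
  magnetometry_rel: 0.01
  nmrd_rel: 0.01         # relative rate error of field-cycling measurements
nmrd:
  n_freq: 32
  temperature: 21.5      # Celsius
report_digits: 1
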