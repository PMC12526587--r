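# Non-homologous-style task: the two domains are acquired on different
# spectrometer resolutions (different grid lengths), so the pipeline must
# go through PCA harmonization onto one shared basis before adaptation.
name: nonhomologous_like
seed: 1
grid: {points: 600, from: 500.0, to: 2000.0}
target_grid: {points: 480, from: 500.0, to: 2000.0}
peaks:
  center:         [760.0, 853.0, 1004.0, 1156.0, 1655.0, 924.0, 991.0, 1317.0, 1444.0]
  width:          [10.0,  9.0,   6.0,    9.0,    12.0,   7.0,   7.0,   8.0,    9.0]
  base_amplitude: [0.55,  0.50,  1.00,   0.45,   0.80,   0.35,  0.40,  0.45,   0.55]
  class_effect:   [0.0,   0.0,   0.0,    0.0,    0.0,    0.40,  0.40,  0.40,   0.40]
source_effect_scale: 1.0
target_effect_scale: 0.7
source_counts: {healthy: 45, disease: 44}
target_counts: {healthy: 68, disease: 72}
train_test_ratio: 0.7
source_shift:
  baseline_coeffs: [0.3, 0.2, -0.1, 0.05]
  gain: 1.0
  noise_sd: 0.02
  peak_jitter_sd: 1.0
  peak_response: [1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0]
target_shift:
  baseline_coeffs: [1.0, -0.5, 0.4, -0.2]
  gain: 1.4
  noise_sd: 0.03
  peak_jitter_sd: 2.0
  peak_response: [1.40, 1.30, 1.15, 1.25, 0.70, 0.80, 0.85, 0.75, 0.70]
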