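# Demo run: a q-only 10% enhancement scenario (the pattern optical
# fluctuation analysis attributes to unitary-signal change), a two-group
# resting-calcium comparison, and an FM unloading cohort.
seed: 20260924
stages: [ofa, calcium, fm]
ofa:
  p0: 0.5
  simulate:
    control:   {n_channels: 20, open_prob: 0.5, unitary_amplitude: 1.0, noise_sd: 0.2}
    perturbed: {n_channels: 20, open_prob: 0.5, unitary_amplitude: 1.1, noise_sd: 0.2}
    n_boutons_control: 100
    n_boutons_perturbed: 100
    n_trials: 5
calcium:
  calib: {kd: 460, n_hill: 2.5, dynamic_range: 32.7}  # example constants
  simulate:
    resting_ca: [100, 160]   # nM per group
    n_rois: 100
    noise_cv: 0.05
fm:
  simulate:
    t_half_mean: 20
    t_half_sd: 4
    noise_sd: 2
    n_puncta: 100
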