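# Demo configuration for the evoked-potential pipeline (run_pipeline).
modality: ieeg
seed: 7
n_trials: 60
fs: 2000
noise_sd: 1.0
artifact_rate: 0.05
channels_per_group: 2
stim_group: lateral
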