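# Example simulation config for `erpride simulate`
n_subjects: 2
trials_per_condition: 20
fs: 500
noise_sd: 8
noise_model: ar1
ar_rho: 0.95
contaminate: 0
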