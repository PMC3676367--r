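# Demo configuration for canopynorm::run_pipeline(): a reduced trial
# (48 genotypes x 2 replicates) that runs in a few seconds. Keys match
# the arguments of run_config(); see ?run_config for units and defaults.
n_genotypes: 48
n_reps: 2
plots_per_row: 16
block_size: 8
n_days: 3
sigma_g: 0.4
n_mc_reps: 199
k_extreme: 5
alpha: 0.05
trial_id: demo
seed: 2011
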