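# example flat configuration for `tacsloop full --config ...`
# keys are arguments of simulation_config() and run_config()
n_subjects: 3
n_blocks: 2
trials_per_block: 10
rest_dur: 20
suppression_depth: 0.3
suppression_tau: 150
seed: 7
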