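prevalence: 0.1
rho: 0.3
hypothesis: alternative
mechanism: none
n_reps: 100
seed: 101

prevalence: 0.1
rho: 0.3
hypothesis: alternative
mechanism: MCAR
dropout_pattern: equal
n_reps: 100
seed: 102

prevalence: 0.1
rho: 0.3
hypothesis: alternative
mechanism: MAR1
dropout_pattern: unequal1
n_reps: 100
seed: 103

prevalence: 0.1
rho: 0.3
hypothesis: null
mechanism: MAR1
dropout_pattern: unequal2
n_reps: 100
seed: 104
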