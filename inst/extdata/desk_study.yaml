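# Desk-scale baseline-vs-RTX phantom study configuration
# (read with read_study_config())
scale: desk
n_baseline: 18
n_rtx: 9
k: 10
q: 0.05
alpha: 0.05
n_perm: 1000
n_random_sw: 20
seed: 1
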