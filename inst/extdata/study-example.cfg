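# Frailty-study configuration (key = value); see read_study_config() for
# defaults. This desk-scale example runs in about a minute.
n_families = 100
beta = 0
s = 3
replicates = 20
seed = 1
maf_min = 0.02
maf_max = 0.1
n_variants = 50
panel_samples = 500
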