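# Default pipeline configuration for the bundled synthetic study.
# Thresholds: alpha/lfc_min drive the DEG direction calls; r_min/top_n the
# correlation modules; top_terms the enrichment report; k/tau the perturbagen
# ranking and contradictory-impact filter.
seed: 1
alpha: 0.05
lfc_min: 0.25
mt_method: bh
scale_factor: 10000
n_variable: 300
r_min: 0.3
top_n: 50
top_terms: 5
guard_term_patterns: MHC
k: 50
tau: 0.5
dose: 10 uM
time: 24 h
pseudocount: 0
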