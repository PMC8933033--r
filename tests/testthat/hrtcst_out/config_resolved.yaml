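abundance: missing.tsv
metadata: ~
ec: ~
pathways: ~
out: hrtcst_out
seed: 1.0
k: ~
k_min: 2.0
k_max: 20.0
min_fraction: 0.01
min_datasets: 2.0
core_prevalence: 0.85
presence_threshold: 0.0
single_project_exclude: yes
n_permutations: 1000.0
highlight: 0.15
gradient_order:
- nasal
- throat
- lung
abundance_cut: 0.01
presence_min_prevalence: 0.25
drop_groups: other
version: 0.1.0
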