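# Small demo scenario for run_pipeline(): all detection thresholds at their
# standard values, 1,000 hotspot shuffles, a 5% scale cohort.
seed: 1
min_mapq: 10
min_support: 4
min_depth: 5
min_qual: 50
merge_window: 50
bin_width: 1.0e7
n_iter: 1000
alpha: 0.05
cohort_scale: 0.05
read_depth: 30
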