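# Demonstration pipeline configuration: a three-day simulated ward stay
# with declining activity, a modest synthetic state sample for tree
# training, and a small re-identification benchmark. Completes in a few
# minutes on one CPU.
seed: 42
days: 3
period: 5
motion_threshold: 0.05
still_threshold: 0.02
hr_margin: 10
kth: 12.5
tree_max_depth: 3
tree_min_samples: 6
n_states: 1000
vocab_k: 64
reid_per_class: 10
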