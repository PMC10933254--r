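# Example study configuration (scaled far below the defaults so it runs
# in seconds; remove the overrides to reproduce the full design).
seed: 20240312
n_per_group: 50
budget: 3
boot_reps: 100
cohort:
  n_users: 80
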