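# Tiny demonstration configuration: 200 proposed patients, one arm,
# shortened trial. Finishes in well under a minute on one CPU.
n_proposed: 200
seed: 20
eps: 0.01
dose_mg_per_kg: 10
interval_days: 14
duration_days: 200
arms: masked
growth_grid_days: 10
omics_n: 300
analyses: [prcc, biomarkers, median_split]
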