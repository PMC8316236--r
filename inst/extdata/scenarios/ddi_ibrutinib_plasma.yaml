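# Paired plasma DDI: vincristine 2 mg IV with and without ibrutinib 560 mg
# QD at steady state; worst-case poor-metabolizer population.
name: ddi_ibrutinib_plasma
victim: vincristine
victim_regimen: {route: iv_infusion, amount: 2.0, infusion_duration: 0.25}
genotype_override: all_poor
population:
  n_trials: 5
  n_subjects_per_trial: 5
  age_range: [20, 90]
  proportion_female: 0.47
  cyp3a5_nonexpressor_frequency: 0.83
  iiv_cv: 0.30
horizon: 96
lloq: 0.05
sites: [plasma]
perpetrators:
- {name: ibrutinib, amount: 560.0, interval: 24.0, lead_in: 168.0}
ic50_divisor: 1
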