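# Muscle-site DDI, deterministic worst-case poor-metabolizer reference
# subject: vincristine 2 mg IV with/without acalabrutinib 100 mg BID BID.  Muscle
# exposure is the 0-24 h AUC of the permeability-limited muscle organ.
name: ddi_acalabrutinib_muscle
victim: vincristine
victim_regimen: {route: iv_infusion, amount: 2.0, infusion_duration: 0.25}
genotype_override: all_poor
use_reference_subject: true
horizon: 24
lloq: 0.05
sites: [plasma, muscle]
perpetrators:
- {name: acalabrutinib, amount: 100.0, interval: 12.0, lead_in: 168.0}
ic50_divisor: 1
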