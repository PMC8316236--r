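# Itraconazole verification: qualitative attribution of the vincristine
# interaction to P-gp vs CYP3A4/5 inhibition (placeholder perpetrator
# inputs; see the itraconazole compound file).
name: itraconazole_verification
victim: vincristine
victim_regimen: {route: iv_infusion, amount: 2.0, infusion_duration: 0.25}
genotype_override: all_poor
use_reference_subject: true
horizon: 96
lloq: 0.05
sites: [plasma]
perpetrators:
- {name: itraconazole, amount: 200.0, interval: 24.0, lead_in: 336.0}
ic50_divisor: 1
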