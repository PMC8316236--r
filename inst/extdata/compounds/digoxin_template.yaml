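# Digoxin - TEMPLATE ONLY.  Probe P-gp substrate; fill in transporter
# kinetics before use.
schema_version: 1
name: digoxin
provenance: TEMPLATE - placeholder physicochemistry; substrate-side kinetics not parameterized.
units:
  molecular_weight: g/mol
molecular_weight: 780.94
log_p: 1.26
compound_class: neutral
blood_to_plasma: 1.0
fu_plasma: 0.75
route: oral
absorption:
  ka: 1.0
  f_abs: 0.7
  dose_regimen_default:
    route: oral
    amount: 0.25
    interval: 24.0
    n_doses: 7
    lead_in: 168.0
disposition:
  cl_f: 7.0
  v_f: 475.0
inhibition: []
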