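# Venetoclax - TEMPLATE ONLY.  P-gp substrate (Caco-2 net efflux ratio 13)
# whose full interaction modeling needs a parameter set not shipped here;
# fill in disposition/kinetics before use.
schema_version: 1
name: venetoclax
provenance: TEMPLATE - placeholder physicochemistry; substrate-side kinetics not parameterized.
units:
  molecular_weight: g/mol
molecular_weight: 868.44
log_p: 7.9
compound_class: neutral
blood_to_plasma: 0.6
fu_plasma: 0.00013
route: oral
absorption:
  ka: 0.3
  f_abs: 1.0
  dose_regimen_default:
    route: oral
    amount: 400.0
    interval: 24.0
    n_doses: 7
    lead_in: 168.0
disposition:
  cl_f: 13.0
  v_f: 400.0
inhibition: []
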