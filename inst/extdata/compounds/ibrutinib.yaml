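# Ibrutinib - perpetrator (strong P-gp inhibitor in vitro).
# Simplified one-compartment oral disposition using published clinical PK
# constants (first-pass-inclusive CL/F and V/F; 560 mg QD).  P-gp IC50
# values from cell-based (5 uM) and vesicular (6 uM) transport assays; Ki =
# IC50 convention.  Site enrichment factors translate unbound plasma into
# the unbound concentration at each interaction site (hepatic inlet plus
# intracellular accumulation for liver; tissue accumulation for muscle);
# the liver and muscle factors are calibration constants fixed once against
# the reference plasma and muscle interaction magnitudes (methods
# vignette).
schema_version: 1
name: ibrutinib
provenance: >-
  Clinical PK constants: published popPK of ibrutinib 560 mg QD (high
  first-pass; apparent CL/F ~560 L/h, t1/2 ~6 h, ka ~0.8/h).  IC50s:
  cell-based and vesicle P-gp inhibition assays.  Site enrichment: package
  calibration, see methods vignette.
units:
  molecular_weight: g/mol
  ic50: uM
  cl_f: L/h
  v_f: L
  ka: 1/h
molecular_weight: 440.5
log_p: 3.97
compound_class: neutral
blood_to_plasma: 1.0
fu_plasma: 0.03
route: oral
absorption:
  ka: 0.8
  f_abs: 1.0
  dose_regimen_default:
    route: oral
    amount: 560.0
    interval: 24.0
    n_doses: 7
    lead_in: 168.0
disposition:
  cl_f: 560.0
  v_f: 4850.0
site_enrichment:
  liver: 150.0
  muscle: 72.958
  kidney: 1.0
inhibition:
- target: P-gp
  ic50: 5.0
  assay_system: cell_based
  ki_convention: ki_equals_ic50
  sensitivity_divisor: 1.0
- target: P-gp
  ic50: 6.0
  assay_system: vesicle
  ki_convention: ki_equals_ic50
  sensitivity_divisor: 1.0
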