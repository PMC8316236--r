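# Acalabrutinib - perpetrator (weak P-gp inhibitor in vitro).
# Simplified one-compartment oral disposition with published clinical PK
# constants (100 mg BID; short half-life).  P-gp IC50 98 uM (cell-based)
# and 57 uM (vesicle); Ki = IC50 convention.  Site enrichment factors are
# modest, consistent with its lower lipophilicity relative to ibrutinib.
schema_version: 1
name: acalabrutinib
provenance: >-
  Clinical PK constants: published popPK of acalabrutinib 100 mg BID
  (CL/F ~160 L/h, t1/2 ~1.5 h, ka ~2/h).  IC50s: cell-based and vesicle
  P-gp inhibition assays.
units:
  molecular_weight: g/mol
  ic50: uM
  cl_f: L/h
  v_f: L
  ka: 1/h
molecular_weight: 465.5
log_p: 2.0
compound_class: neutral
blood_to_plasma: 0.8
fu_plasma: 0.025
route: oral
absorption:
  ka: 2.0
  f_abs: 1.0
  dose_regimen_default:
    route: oral
    amount: 100.0
    interval: 12.0
    n_doses: 14
    lead_in: 168.0
disposition:
  cl_f: 160.0
  v_f: 346.0
site_enrichment:
  liver: 10.0
  muscle: 3.0
  kidney: 1.0
inhibition:
- target: P-gp
  ic50: 98.0
  assay_system: cell_based
  ki_convention: ki_equals_ic50
  sensitivity_divisor: 1.0
- target: P-gp
  ic50: 57.0
  assay_system: vesicle
  ki_convention: ki_equals_ic50
  sensitivity_divisor: 1.0
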