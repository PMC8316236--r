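# Itraconazole - perpetrator used for verification of the P-gp vs CYP3A4/5
# contributions to victim elimination.  PLACEHOLDER perpetrator inputs:
# the study's own itraconazole + hydroxy-itraconazole parameter set is not
# reproduced in its main text, so this file ships documented published
# defaults; the CYP3A and P-gp potencies notionally fold in the
# hydroxy-itraconazole contribution.  Edit to taste.
schema_version: 1
name: itraconazole
provenance: >-
  PLACEHOLDER published defaults: itraconazole 200 mg QD popPK
  (CL/F ~20 L/h, t1/2 ~24 h), strong CYP3A inhibition (Ki ~0.013 uM
  unbound, parent + hydroxy metabolite lumped), moderate P-gp inhibition
  (IC50 ~1 uM).  Not the study's supplemental parameter set.
units:
  molecular_weight: g/mol
  ic50: uM
  cl_f: L/h
  v_f: L
  ka: 1/h
molecular_weight: 705.6
log_p: 5.7
compound_class: neutral
blood_to_plasma: 0.7
fu_plasma: 0.036
route: oral
absorption:
  ka: 0.5
  f_abs: 1.0
  dose_regimen_default:
    route: oral
    amount: 200.0
    interval: 24.0
    n_doses: 14
    lead_in: 336.0
disposition:
  cl_f: 20.0
  v_f: 700.0
site_enrichment:
  liver: 15.0
  muscle: 3.0
  kidney: 1.0
inhibition:
- target: P-gp
  ic50: 1.0
  assay_system: vesicle
  ki_convention: ki_equals_ic50
  sensitivity_divisor: 1.0
- target: CYP3A4
  ic50: 0.013
  assay_system: cell_based
  ki_convention: ki_equals_ic50
  sensitivity_divisor: 1.0
- target: CYP3A5
  ic50: 0.013
  assay_system: cell_based
  ki_convention: ki_equals_ic50
  sensitivity_divisor: 1.0
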