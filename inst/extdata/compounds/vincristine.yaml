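# Vincristine - victim compound.
# Physicochemistry, binding, enzyme and transporter kinetics from the
# model's declared input set (microsomal CYP3A4/3A5 kinetics per expressor
# class; P-gp Jmax/Km from MDCK-derived assays with RAF/REF 1.5).
# Organ-level scalars (ps_scalar, cells_million, pgp_scalar, iw_binding)
# and additional_systemic_cl are model calibration constants: fixed once so
# the simulated Vss, renal clearance, total clearance, elimination-pathway
# split and terminal-phase kinetics match the reference clinical values;
# see the package methods vignette.
schema_version: 1
name: vincristine
provenance: >-
  Physicochemical and in vitro parameters: declared PBPK input set
  (product information, internal assay data, literature Vss and renal CL).
  Calibrated scalars: package calibration, see methods vignette.
units:
  molecular_weight: g/mol
  v_max: pmol/min/mg microsomal protein
  k_m: uM
  j_max: pmol/min/million cells
  cl_pd: uL/min/million cells
  additional_systemic_cl: L/h
  vss_target: L/kg
  renal_cl_observed: L/h
molecular_weight: 824.96
log_p: 2.67
compound_class: monoprotic_acid
pka: 5.15
blood_to_plasma: 1.2
fu_plasma: 0.51
fu_mic: 0.75
vss_target: 1.64
renal_cl_observed: 4.18
route: iv_infusion
additional_systemic_cl: 11.185
enzyme_kinetics:
- enzyme: CYP3A5
  expressor_class: extensive
  v_max: 416.0
  k_m: 18.5
  abundance: 1.9055
- enzyme: CYP3A5
  expressor_class: poor
  v_max: 114.0
  k_m: 89.8
  abundance: 1.9055
- enzyme: CYP3A4
  expressor_class: n/a
  v_max: 0.9
  k_m: 19.5
  abundance: 1.9055
transporter_kinetics:
- transporter: P-gp
  organ: liver
  j_max: 77.0
  k_m: 17.1
  raf_ref: 1.5
- transporter: P-gp
  organ: kidney
  j_max: 77.0
  k_m: 17.1
  raf_ref: 1.5
- transporter: P-gp
  organ: muscle
  j_max: 77.0
  k_m: 17.1
  raf_ref: 1.5
permeability:
  liver:
    cl_pd: 0.37
    fu_iw: 0.036
    fu_ew: 1.0
    cells_per_g: 118.0
    ps_scalar: 4053.5
    pgp_scalar: 0.2672
    iw_binding: 246.57
    vasc_ps_per_flow: 51.813
  kidney:
    cl_pd: 0.1
    fu_iw: 0.036
    fu_ew: 1.0
    cells_million: 1182650.0
  muscle:
    cl_pd: 0.1
    fu_iw: 0.0771
    fu_ew: 0.8
    cells_million: 2200000.0
    pgp_scalar: 0.023403
    iw_binding: 1.0
inhibition: []
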