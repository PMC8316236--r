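# Reference human system parameters for a 70-kg adult.
# Values are standard published physiology compilations (organ weights and
# regional blood flows: ICRP reference anatomical data and Davies & Morris,
# Pharm Res 1993; tissue composition: Rodgers & Rowland mechanistic Kp
# tissue data; liver scalars: consensus human hepatocellularity and
# microsomal protein recovery).  Organ volumes scale linearly with body
# weight; blood flows and GFR scale with (BW/70)^0.75.
schema_version: 1
reference_body_weight_kg: 70
cardiac_output_l_h: 389
hematocrit: 0.45
blood_v_frac: 0.079
arterial_frac: 0.333333333333333
gfr_l_h: 7.2
mppgl_mg_per_g: 40
hpgl_million_per_g: 118
ph_plasma: 7.4
ph_ew: 7.4
ph_iw: 7.0
plasma_f_nl: 0.0023
plasma_f_npl: 0.0013
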