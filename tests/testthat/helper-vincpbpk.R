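# Shared fixtures: all built in code at test time.

vincristine_record <- function() {
  load_compound(vincpbpk_file("compounds", "vincristine.yaml"))
}

ibrutinib_record <- function() {
  load_compound(vincpbpk_file("compounds", "ibrutinib.yaml"))
}

# A minimal inert compound: no enzymes, no transporters, optional
# first-order systemic clearance only; permeability zones switched off
# (ps_scalar 0).  With near-zero tissue partitioning the whole body
# collapses to the blood pool plus the vascular zones - the analytic
# one-compartment configuration.
inert_compound <- function(cl_add = 0, kp_ratio = 1) {
  validate_compound(list(
    name = "probe", molecular_weight = 500, log_p = 0,
    compound_class = "neutral", blood_to_plasma = 1, fu_plasma = 1,
    route = "iv_infusion", additional_systemic_cl = cl_add,
    permeability = list(
      liver = list(cl_pd = 1e-9, fu_iw = 1, fu_ew = 1, cells_per_g = 1,
                   ps_scalar = 0, vasc_ps_per_flow = 0),
      kidney = list(cl_pd = 1e-9, fu_iw = 1, fu_ew = 1, cells_million = 1,
                    ps_scalar = 0, vasc_ps_per_flow = 0),
      muscle = list(cl_pd = 1e-9, fu_iw = 1, fu_ew = 1, cells_million = 1,
                    ps_scalar = 0, vasc_ps_per_flow = 0))
  ))
}

flat_partitions <- function(phys, kp = 1e-9) {
  kps <- setNames(rep(kp, nrow(phys$organs)), phys$organs$organ)
  structure(list(kp = kps, kp_scalar = 1, method = "rodgers_rowland_2",
                 compound = "probe"), class = "partition_set")
}

# Effective one-compartment volume of the blood-only configuration:
# arterial + venous blood plus the vascular zones of the three
# permeability-limited organs (lung and tissues hold ~nothing at Kp 1e-9).
blood_volume_effective <- function(model) {
  phys <- model$subject$physiology
  v <- phys$v_art + phys$v_ven
  for (org in c("liver", "kidney", "muscle")) {
    row <- phys$organs[phys$organs$organ == org, ]
    v <- v + row$vasc_frac * row$volume
  }
  v
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}
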