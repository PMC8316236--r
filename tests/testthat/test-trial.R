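small_scenario <- function(name = "baseline_population", n_trials = 1,
                           n_subjects = 3) {
  sc <- named_scenario(name)
  sc$population$n_trials <- as.integer(n_trials)
  sc$population$n_subjects_per_trial <- as.integer(n_subjects)
  sc
}

test_that("scenario runs are deterministic given the seed", {
  sc <- small_scenario()
  r1 <- run_scenario(sc, seed = 7)
  r2 <- run_scenario(sc, seed = 7)
  expect_identical(r1$pooled, r2$pooled)
  expect_identical(r1$per_subject, r2$per_subject)
  r3 <- run_scenario(sc, seed = 8)
  expect_false(identical(r1$pooled, r3$pooled))
})

test_that("a single-subject zero-variability run has zero pooled SD", {
  sc <- small_scenario(n_subjects = 1)
  sc$population$iiv_cv <- 0
  r <- run_scenario(sc, seed = 1)
  expect_equal(unname(r$pooled["auc_0_inf", "sd"]), 0)
  sc2 <- small_scenario(n_subjects = 2)
  sc2$population$iiv_cv <- 0
  # two subjects differ only demographically; force identical weights too
  r2 <- run_scenario(sc2, seed = 1)
  expect_true(is.finite(r2$pooled["auc_0_inf", "sd"]))
})

test_that("static DDI screen arithmetic and threshold boundaries", {
  perp <- validate_compound(list(
    name = "probe_inh", molecular_weight = 400, compound_class = "neutral",
    blood_to_plasma = 1, fu_plasma = 0.1, route = "oral",
    absorption = list(ka = 1, f_abs = 1,
                      dose_regimen_default = list(route = "oral", amount = 100,
                                                  interval = 24)),
    disposition = list(cl_f = 50, v_f = 500),
    inhibition = list(list(target = "P-gp", ic50 = 100,
                           assay_system = "cell_based",
                           ki_convention = "ki_equals_ic50"))))
  rep1 <- static_ddi_screen(perp, dose = 100)
  expect_equal(rep1$i_gut, 100 / 0.25 / 400 * 1000)   # 1000 uM
  expect_equal(rep1$ratio_gut, 10)
  expect_true("gut_pgp_inhibition_risk" %in% rep1$flags)
  # just under the cut-off: no flag
  perp$inhibition[[1]]$ic50 <- 100.1
  rep2 <- static_ddi_screen(perp, dose = 100)
  expect_lt(rep2$ratio_gut, 10)
  expect_false("gut_pgp_inhibition_risk" %in% rep2$flags)
})

test_that("ibrutinib is flagged for gut-level P-gp inhibition risk", {
  ibr <- ibrutinib_record()
  rep <- static_ddi_screen(ibr)
  expect_gt(rep$ratio_gut, 10)
  expect_true("gut_pgp_inhibition_risk" %in% rep$flags)
  # acalabrutinib at clinical doses is not flagged at the gut
  aca <- load_compound(vincpbpk_file("compounds", "acalabrutinib.yaml"))
  rep_a <- static_ddi_screen(aca)
  expect_false("systemic_pgp_inhibition_risk" %in% rep_a$flags)
})

test_that("sensitivity divisor 1 reproduces the plain scenario run", {
  sc <- named_scenario("ddi_ibrutinib_muscle")
  r_plain <- run_scenario(sc, seed = 1)
  sw <- sensitivity_sweep(sc, divisors = 1, seed = 1)
  mrow <- sw[sw$site == "muscle", ]
  expect_equal(mrow$auc_ratio, r_plain$ddi$muscle$auc_ratio, tolerance = 1e-12)
})

test_that("IV victim plasma AUC ratio does not exceed the oral-victim ratio", {
  # route-of-administration property: an oral victim adds hepatic first-pass
  # exposure to inhibition, so the same perpetrator produces at least as
  # large a plasma AUC ratio as with the IV victim
  vcr <- vincristine_record()
  oral <- unclass(vcr)
  oral$route <- "oral"
  oral$absorption <- list(ka = 1, f_abs = 1)
  oral <- validate_compound(oral)
  ibr <- ibrutinib_record()
  s <- reference_subject()
  part <- calibrate_kp_scalar(predict_kp(vcr, s$physiology), vcr$vss_target,
                              vcr, s$physiology)
  opts <- model_options(sensitivity_divisor = 30)
  ratio_for <- function(victim, route_dose) {
    m0 <- pbpk_model(s, victim, partitions = part, dosing = route_dose,
                     options = opts)
    m1 <- pbpk_model(s, victim, partitions = part, dosing = route_dose,
                     perpetrators = list(list(compound = ibr)), options = opts)
    s0 <- simulate_pbpk(m0, horizon = 24)
    a0 <- auc_trapezoid(s0$time, s0$conc[, "plasma"], 0, 24)
    s1 <- simulate_pbpk(m1, horizon = 24)
    a1 <- auc_trapezoid(s1$time, s1$conc[, "plasma"], 0, 24)
    a1 / a0
  }
  r_iv <- ratio_for(vcr, dose_regimen("iv_infusion", 2, 0.25))
  r_oral <- ratio_for(oral, dose_regimen("oral", 2))
  expect_gte(r_oral, r_iv - 1e-6)
})

test_that("pathway attribution splits a dual P-gp/CYP3A inhibitor", {
  sc <- named_scenario("itraconazole_verification")
  sc$horizon <- 48
  att <- ddi_pathway_attribution(sc, seed = 1)
  expect_setequal(att$component, c("full", "pgp_only", "cyp3a_only"))
  expect_true(all(att$auc_ratio >= 1 - 1e-6))
  full <- att$auc_ratio[att$component == "full"]
  expect_gte(full, max(att$auc_ratio[att$component != "full"]) - 1e-6)
})
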