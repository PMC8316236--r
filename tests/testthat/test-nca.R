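test_that("NCA reproduces closed-form values for a monoexponential profile", {
  k <- 0.0693                     # t1/2 = 10 h
  tt <- seq(0, 96, by = 1)
  cc <- 100 * exp(-k * tt)
  dose <- 2                       # mg; true CL = dose/AUC
  auc_true <- 100 / k
  res <- nca(tt, cc, dose = dose, body_weight = 70)
  expect_equal(res$half_life, 10, tolerance = 0.005)
  expect_equal(res$auc_0_inf, auc_true, tolerance = 0.005 * auc_true)
  cl_true <- dose * 1e6 / auc_true / 60
  expect_equal(res$cl, cl_true, tolerance = 0.005 * cl_true)
  vz_true <- (dose * 1e6 / auc_true) / k / 1000 / 70
  expect_equal(res$vd, vz_true, tolerance = 0.005 * vz_true)
  auc24_true <- 100 / k * (1 - exp(-24 * k))
  expect_equal(res$auc_0_24, auc24_true, tolerance = 0.005 * auc24_true)
})

test_that("AUC x CL is internally consistent with the dose", {
  # Table-layout arithmetic: 2 mg at CL 666 mL/min gives AUC ~ 50.1 ng h/mL
  expect_equal(2e6 / (666 * 60), 50.05, tolerance = 1e-3)
  # and NCA reports CL = dose/AUC by construction on any profile
  tt <- seq(0, 96, by = 0.5)
  cc <- 80 * exp(-0.05 * tt) + 5 * exp(-0.01 * tt)
  res <- nca(tt, cc, dose = 2)
  expect_equal(res$cl * 60 * res$auc_0_inf, 2e6, tolerance = 1)
})

test_that("degenerate profiles are rejected or flagged", {
  tt <- seq(0, 24, by = 1)
  expect_error(nca(tt, rep(0, length(tt)), dose = 2), "positive quantifiable")
  # censoring everything below a huge LLOQ leaves nothing
  expect_error(nca(tt, 100 * exp(-0.1 * tt), dose = 2, lloq = 1e6),
               "positive quantifiable")
  # too few tail points: no terminal phase, flagged not errored
  res <- nca(c(0, 1, 2), c(10, 8, 100), dose = 2)
  expect_false(res$terminal_phase)
  expect_true(is.na(res$half_life))
})

test_that("LLOQ censoring excludes points from the terminal regression", {
  tt <- c(seq(0, 12, 0.5), 24, 36, 48, 72, 96)
  cc <- 100 * exp(-0.3 * tt) + 0.04 * exp(-0.005 * tt)
  res_all <- nca(tt, cc, dose = 2)
  res_cens <- nca(tt, cc, dose = 2, lloq = 0.05)
  # uncensored regression sees the shallow tail; censored one does not
  expect_gt(res_all$half_life, res_cens$half_life)
})

test_that("geometric-mean DDI ratios match hand arithmetic", {
  mk <- function(auc, cmax) list(auc_0_24 = auc, cmax = cmax)
  with_p <- list(mk(1.1, 1.0), mk(1.2, 1.0), mk(1.25, 1.0))
  without <- list(mk(1, 1), mk(1, 1), mk(1, 1))
  s <- ddi_ratios(with_p, without)
  expect_equal(s$auc_ratio, (1.1 * 1.2 * 1.25)^(1 / 3), tolerance = 1e-9)
  expect_equal(round(s$auc_ratio, 4), 1.1817)
  # identity: identical lists give GM exactly 1 with a degenerate interval
  id <- ddi_ratios(without, without)
  expect_equal(id$auc_ratio, 1)
  expect_equal(id$auc_ratio_ci90, c(1, 1))
  # scaling: doubling every exposure doubles the GM ratio
  doubled <- lapply(without, function(x) mk(2 * x$auc_0_24, 2 * x$cmax))
  expect_equal(ddi_ratios(doubled, without)$auc_ratio, 2)
  expect_error(ddi_ratios(with_p[1:2], without), "same number")
})

test_that("elimination decomposition fractions always sum to one", {
  vcr <- vincristine_record()
  s <- reference_subject()
  part <- calibrate_kp_scalar(predict_kp(vcr, s$physiology), vcr$vss_target,
                              vcr, s$physiology)
  sim <- simulate_pbpk(pbpk_model(s, vcr, partitions = part), horizon = 96)
  d <- suppressWarnings(elimination_decomposition(sim))
  expect_equal(d$fm_cyp3a + d$fe_pgp + d$fe_renal_filtration + d$fe_unassigned,
               1, tolerance = 1e-9)
  expect_equal(d$fm_cyp3a + d$fe_total, 1, tolerance = 1e-12)
})

test_that("single-pathway models decompose to a single fraction", {
  s <- reference_subject()
  probe <- inert_compound(cl_add = 2)
  sim <- simulate_pbpk(pbpk_model(s, probe,
                                  partitions = flat_partitions(s$physiology)),
                       horizon = 300)
  d <- elimination_decomposition(sim)
  expect_equal(d$fe_unassigned, 1, tolerance = 1e-9)
  expect_equal(d$fm_cyp3a, 0)
})

test_that("NCA recovers the true clearance of a one-compartment probe", {
  s <- reference_subject()
  probe <- inert_compound(cl_add = 2)
  sim <- simulate_pbpk(pbpk_model(s, probe,
                                  partitions = flat_partitions(s$physiology)),
                       horizon = 48)
  res <- nca(sim$time, sim$conc[, "plasma"], dose = 2)
  expect_lt(res$extrapolated_fraction, 0.05)
  cl_true_ml_min <- 2 * 1000 / 60
  expect_equal(res$cl, cl_true_ml_min, tolerance = 0.02 * cl_true_ml_min)
})
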