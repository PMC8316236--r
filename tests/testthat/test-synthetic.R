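sim_for_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      vcr <- vincristine_record()
      s <- reference_subject()
      part <- calibrate_kp_scalar(predict_kp(vcr, s$physiology),
                                  vcr$vss_target, vcr, s$physiology)
      cache <<- simulate_pbpk(pbpk_model(s, vcr, partitions = part),
                              horizon = 96)
    }
    cache
  }
})

test_that("zero residual error reproduces the model predictions exactly", {
  sim <- sim_for_synth()
  times <- c(0.5, 1, 2, 4, 8, 24)
  ds <- generate_observed(sim, times, error_cv = 0, lloq = 1e-6, seed = 1)
  pred <- approx(sim$time, sim$conc[, "plasma"], xout = times)$y
  expect_equal(ds$data$conc, pred)
  expect_false(any(ds$data$bql_flag))
})

test_that("datasets are regenerable from their seed", {
  sim <- sim_for_synth()
  times <- c(0.5, 1, 2, 4, 8, 24, 48)
  d1 <- generate_observed(sim, times, error_cv = 0.2, n_subjects = 3, seed = 42)
  d2 <- generate_observed(sim, times, error_cv = 0.2, n_subjects = 3, seed = 42)
  expect_identical(d1$data, d2$data)
  d3 <- generate_observed(sim, times, error_cv = 0.2, n_subjects = 3, seed = 43)
  expect_false(identical(d1$data, d3$data))
})

test_that("the empirical residual CV matches the nominal 20%", {
  sim <- sim_for_synth()
  ds <- generate_observed(sim, times = 2, error_cv = 0.2, lloq = 1e-9,
                          n_subjects = 1000, seed = 5)
  cv <- sd(ds$data$conc) / mean(ds$data$conc)
  expect_lt(abs(cv - 0.2), 0.02)
})

test_that("an LLOQ above all predictions censors the whole dataset", {
  sim <- sim_for_synth()
  ds <- generate_observed(sim, times = c(24, 48, 96), error_cv = 0,
                          lloq = 1e6, seed = 1)
  expect_true(all(ds$data$bql_flag))
  expect_true(ds$all_censored)
  expect_true(all(is.na(ds$data$conc)))
})

test_that("observed datasets round-trip through CSV with a JSON sidecar", {
  sim <- sim_for_synth()
  ds <- generate_observed(sim, times = c(1, 4, 24), error_cv = 0.2,
                          n_subjects = 2, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_observed(ds, path)
  back <- read.csv(path)
  expect_equal(back$conc, ds$data$conc)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$seed, 9)
  expect_equal(side$error_cv, 0.2)
})

test_that("assay plates regenerate from seed and feed the fitters", {
  truth <- list(ic50 = 57, hill = 1, top = 1, bottom = 0)
  design <- c(0.5, 2, 10, 57, 200, 500)
  p1 <- generate_assay_plate(truth, design, model = "vesicle", noise_cv = 0,
                             seed = 1)
  fit <- fit_assay_plate(p1)
  expect_equal(fit$ic50, 57, tolerance = 1e-6)
  p2 <- generate_assay_plate(truth, design, model = "vesicle",
                             noise_cv = 0.1, seed = 3)
  p3 <- generate_assay_plate(truth, design, model = "vesicle",
                             noise_cv = 0.1, seed = 3)
  expect_identical(p2$responses, p3$responses)
  expect_error(generate_assay_plate(truth, numeric(0)), "empty")
})

test_that("a single-concentration design is unidentifiable downstream", {
  truth <- list(km = 17.1, vmax = 77)
  plate <- generate_assay_plate(truth, design = rep(10, 6), model = "mm",
                                noise_cv = 0, seed = 1)
  expect_error(fit_assay_plate(plate), "distinct")
})

test_that("full round trip: synthetic observed -> NCA recovers model CL", {
  sim <- sim_for_synth()
  times <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 36, 48, 72, 96)
  truth_nca <- nca_from_sim(sim, times = times, lloq = 0.05)
  ds <- generate_observed(sim, times, error_cv = 0.2, lloq = 0.05,
                          n_subjects = 25, seed = 17)
  cls <- vapply(split(ds$data, ds$data$subject), function(d) {
    res <- try(nca(d$time, d$conc, dose = sim$dose_mg), silent = TRUE)
    if (inherits(res, "try-error") || !isTRUE(res$terminal_phase))
      return(NA_real_)
    res$cl
  }, numeric(1))
  expect_lt(abs(mean(cls, na.rm = TRUE) - truth_nca$cl) / truth_nca$cl, 0.10)
})
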