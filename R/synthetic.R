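# Synthetic data generation: pseudo-observed concentration-time datasets
# (model prediction plus multiplicative log-normal residual error with LLOQ
# censoring) and in vitro assay plates generated from the fitted-curve
# equations plus noise.  Every dataset is regenerable from its seed and
# generating-parameter record.

#' Generate a pseudo-observed concentration-time dataset
#'
#' Samples the simulated plasma profile at the design times for each of
#' `n_subjects` virtual observations, applies multiplicative log-normal
#' residual error with the stated CV, and censors values below the LLOQ.
#' Residual error is the only source of between-replicate variation; the
#' model prediction is shared (use a population scenario for parameter
#' variability).
#'
#' @param sim A `pbpk_sim` for the generating model.
#' @param times Sampling schedule (h); must be non-empty and within the
#'   simulated horizon.
#' @param error_cv Residual coefficient of variation (fraction, >= 0;
#'   default 0.20).
#' @param lloq Lower limit of quantification in ng/mL (default 0.1);
#'   censored points carry `bql_flag = TRUE` and `conc = NA`.
#' @param n_subjects Number of replicate subjects.
#' @param seed Integer seed.
#' @return A `synthetic_observed` object: `data` (subject, time, conc,
#'   bql_flag), the generating record, and `all_censored` flag.
#' @export
generate_observed <- function(sim, times, error_cv = 0.20, lloq = 0.1,
                              n_subjects = 1, seed = 1L) {
  stopifnot(inherits(sim, "pbpk_sim"))
  if (!length(times)) stop_domain("empty sampling schedule")
  if (any(times < 0 | times > max(sim$time)))
    stop_domain("design times must lie within the simulated horizon")
  check_scalar(error_cv, "error_cv", 0)
  pred <- stats::approx(sim$time, sim$conc[, "plasma"], xout = times)$y
  set.seed(seed)
  sdlog <- cv_to_sdlog(error_cv)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    eps <- if (error_cv > 0) rnorm(length(times), 0, sdlog) else
      numeric(length(times))
    conc <- pred * exp(eps)
    bql <- conc < lloq
    conc[bql] <- NA_real_
    rows[[s]] <- data.frame(subject = s, time = times, conc = conc,
                            bql_flag = bql)
  }
  data <- do.call(rbind, rows)
  structure(list(
    data = data,
    generating = list(dose_mg = sim$dose_mg, times = times,
                      error_cv = error_cv, lloq = lloq,
                      n_subjects = n_subjects, seed = as.integer(seed)),
    all_censored = all(data$bql_flag)
  ), class = "synthetic_observed")
}

#' @export
print.synthetic_observed <- function(x, ...) {
  cat(sprintf("<synthetic_observed> %d subjects x %d times, CV %.0f%%, LLOQ %g ng/mL\n",
              x$generating$n_subjects, length(x$generating$times),
              100 * x$generating$error_cv, x$generating$lloq))
  cat(sprintf("  %d/%d points below LLOQ%s\n", sum(x$data$bql_flag),
              nrow(x$data),
              if (x$all_censored) " (all censored: empty-informative)" else ""))
  invisible(x)
}

#' Write a synthetic observed dataset to CSV with a JSON sidecar
#'
#' @param x A `synthetic_observed`.
#' @param path CSV output path; the generating record is written next to it
#'   as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_observed <- function(x, path) {
  stopifnot(inherits(x, "synthetic_observed"))
  write.csv(x$data, path, row.names = FALSE)
  jsonlite::write_json(x$generating, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic in vitro assay plate
#'
#' Responses are computed from the chosen curve model - the
#' linear-concentration inhibition equation (`"cell"`), the
#' log-concentration four-parameter logistic (`"vesicle"`), or
#' Michaelis-Menten transport (`"mm"`) - and multiplied by log-normal noise.
#'
#' @param truth Named list of generating parameters: for `cell`/`vesicle`
#'   `ic50`, `hill`, `top`, `bottom`; for `mm` `km`, `vmax`.
#' @param design Concentration vector (uM, strictly positive).
#' @param model Curve model.
#' @param noise_cv Multiplicative noise CV (fraction).
#' @param replicates Number of replicate wells per concentration (default 3,
#'   the usual plate layout; each replicate gets independent noise).
#' @param seed Integer seed.
#' @return An `assay_plate`: `concentrations` (design expanded over
#'   replicates), `responses`, the truth record and the model label.
#' @export
generate_assay_plate <- function(truth, design, model = c("cell", "vesicle", "mm"),
                                 noise_cv = 0, replicates = 3, seed = 1L) {
  model <- match.arg(model)
  if (!length(design)) stop_domain("empty concentration design")
  if (any(design <= 0)) stop_domain("concentrations must be positive")
  check_scalar(noise_cv, "noise_cv", 0)
  check_scalar(replicates, "replicates", 1)
  design <- rep(design, each = replicates)
  mu <- switch(model,
    cell = truth$bottom + (truth$top - truth$bottom) /
      (1 + (design / truth$ic50)^truth$hill),
    vesicle = truth$bottom + (truth$top - truth$bottom) /
      (1 + 10^((log10(design) - log10(truth$ic50)) * truth$hill)),
    mm = truth$vmax * design / (truth$km + design))
  set.seed(seed)
  eps <- if (noise_cv > 0) rnorm(length(mu), 0, cv_to_sdlog(noise_cv)) else
    numeric(length(mu))
  structure(list(concentrations = design, responses = mu * exp(eps),
                 truth = truth, model = model, replicates = replicates,
                 seed = as.integer(seed), noise_cv = noise_cv),
            class = "assay_plate")
}

#' Fit the matching curve model to an assay plate
#'
#' Dispatches to [fit_ic50_cell()], [fit_ic50_vesicle()] or
#' [fit_mm_transport()] according to the plate's model label.
#'
#' @param plate An `assay_plate`.
#' @return An `ic50_fit`.
#' @export
fit_assay_plate <- function(plate) {
  stopifnot(inherits(plate, "assay_plate"))
  switch(plate$model,
    cell = fit_ic50_cell(plate$concentrations, plate$responses),
    vesicle = fit_ic50_vesicle(log10(plate$concentrations), plate$responses),
    mm = fit_mm_transport(plate$concentrations, plate$responses))
}
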