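# Drug-drug interaction summary statistics and elimination-pathway
# decomposition.

#' Geometric-mean DDI ratios with 90% interval
#'
#' Per-subject exposure ratios (with perpetrator / without), summarized as
#' geometric mean with a log-scale t-based 90% interval.  Inputs are paired
#' by position: element i of both lists is the same virtual subject
#' simulated with and without the perpetrator.
#'
#' @param with_perp,without_perp Lists of [nca()] results (or data frames
#'   with `auc_0_24` and `cmax` columns), same length and subject order.
#' @param pairing `"paired"` (default; requires equal lengths) or
#'   `"population"` (ratio of group geometric means).
#' @param site Label for the exposure site (`"plasma"` or `"muscle"`).
#' @return A `ddi_summary`: `auc_ratio` and `cmax_ratio` geometric means,
#'   90% intervals, and the per-subject ratios.
#' @export
ddi_ratios <- function(with_perp, without_perp,
                       pairing = c("paired", "population"),
                       site = "plasma") {
  pairing <- match.arg(pairing)
  get <- function(lst, f) vapply(lst, function(x) as.numeric(x[[f]]), numeric(1))
  aw <- get(with_perp, "auc_0_24"); ao <- get(without_perp, "auc_0_24")
  cw <- get(with_perp, "cmax"); co <- get(without_perp, "cmax")
  if (pairing == "paired" && length(aw) != length(ao))
    stop_domain("paired inputs must have the same number of subjects")
  gm <- function(x) exp(mean(log(x)))
  ci90 <- function(x) {
    lx <- log(x)
    n <- length(lx)
    if (n < 2 || sd(lx) == 0) return(c(gm(x), gm(x)))
    exp(mean(lx) + c(-1, 1) * qt(0.95, n - 1) * sd(lx) / sqrt(n))
  }
  if (pairing == "paired") {
    ra <- aw / ao; rc <- cw / co
    structure(list(auc_ratio = gm(ra), cmax_ratio = gm(rc),
                   auc_ratio_ci90 = ci90(ra), cmax_ratio_ci90 = ci90(rc),
                   ratios = data.frame(auc_ratio = ra, cmax_ratio = rc),
                   pairing = pairing, site = site, n = length(ra)),
              class = "ddi_summary")
  } else {
    structure(list(auc_ratio = gm(aw) / gm(ao), cmax_ratio = gm(cw) / gm(co),
                   auc_ratio_ci90 = c(NA, NA), cmax_ratio_ci90 = c(NA, NA),
                   ratios = NULL, pairing = pairing, site = site,
                   n = length(aw)),
              class = "ddi_summary")
  }
}

#' @export
print.ddi_summary <- function(x, ...) {
  cat(sprintf("<ddi_summary> site %s, %s, n = %d\n", x$site, x$pairing, x$n))
  cat(sprintf("  AUC ratio  GM %.3f (90%% CI %.3f-%.3f)\n", x$auc_ratio,
              x$auc_ratio_ci90[1], x$auc_ratio_ci90[2]))
  cat(sprintf("  Cmax ratio GM %.3f (90%% CI %.3f-%.3f)\n", x$cmax_ratio,
              x$cmax_ratio_ci90[1], x$cmax_ratio_ci90[2]))
  invisible(x)
}

#' Elimination-pathway decomposition from cumulative fluxes
#'
#' Fractions of elimination by pathway at the simulation horizon,
#' normalized by the total amount eliminated: CYP3A metabolism (fm), P-gp
#' excretion (biliary + renal secretion), renal filtration and the
#' unassigned first-order systemic clearance.  The fractions sum to 1 by
#' construction.
#'
#' @param sim A `pbpk_sim` run to near-complete (>= 99%) elimination; a
#'   shorter run triggers a warning and sets the `extrapolation_flag`.
#' @return An `elimination_decomposition` with fields `fm_cyp3a`,
#'   `fe_total`, `fe_pgp`, `fe_renal_filtration`, `fe_unassigned`,
#'   `fraction_of_dose_eliminated`.
#' @export
elimination_decomposition <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  fl <- sim$fluxes[nrow(sim$fluxes), ]
  total <- fl$total_eliminated
  if (total <= 0) stop_domain("no elimination occurred")
  frac_elim <- total / sim$dose_mg
  flag <- frac_elim < 0.99
  if (flag)
    warning(sprintf("only %.1f%% of dose eliminated; fractions are renormalized",
                    100 * frac_elim), call. = FALSE)
  fm <- (fl$cyp3a4 + fl$cyp3a5) / total
  fe_pgp <- (fl$bile_pgp + fl$urine_pgp) / total
  fe_filt <- fl$urine_filtration / total
  fe_add <- fl$additional / total
  structure(list(fm_cyp3a = fm, fe_total = 1 - fm, fe_pgp = fe_pgp,
                 fe_renal_filtration = fe_filt, fe_unassigned = fe_add,
                 fraction_of_dose_eliminated = frac_elim,
                 extrapolation_flag = flag),
            class = "elimination_decomposition")
}

#' @export
print.elimination_decomposition <- function(x, ...) {
  cat("<elimination_decomposition>\n")
  cat(sprintf("  fm (CYP3A)           %5.1f%%\n", 100 * x$fm_cyp3a))
  cat(sprintf("  fe (total excretion) %5.1f%%\n", 100 * x$fe_total))
  cat(sprintf("    P-gp (bile+urine)  %5.1f%%\n", 100 * x$fe_pgp))
  cat(sprintf("    renal filtration   %5.1f%%\n", 100 * x$fe_renal_filtration))
  cat(sprintf("    unassigned route   %5.1f%%\n", 100 * x$fe_unassigned))
  cat(sprintf("  (%.1f%% of dose eliminated)\n",
              100 * x$fraction_of_dose_eliminated))
  invisible(x)
}

#' Genotype-frequency-weighted elimination decomposition
#'
#' Runs the victim model to near-complete elimination for one reference
#' poor-metabolizer and one extensive-metabolizer subject and averages the
#' pathway fractions with the population CYP3A5 non-expressor frequency
#' (default 0.83): the deterministic expectation of the population
#' decomposition.
#'
#' @param victim A victim `compound_record`.
#' @param nonexpressor_frequency Weight of the poor-metabolizer branch.
#' @param horizon Simulation horizon in h.
#' @param options [model_options()].
#' @return An `elimination_decomposition` (weighted), with attribute
#'   `by_genotype` carrying the two underlying decompositions.
#' @export
weighted_decomposition <- function(victim, nonexpressor_frequency = 0.83,
                                   horizon = 600, options = model_options()) {
  run <- function(genotype) {
    subj <- reference_subject(genotype)
    part <- calibrate_kp_scalar(predict_kp(victim, subj$physiology),
                                victim$vss_target, victim, subj$physiology)
    sim <- simulate_pbpk(pbpk_model(subj, victim, partitions = part,
                                    options = options),
                         horizon = horizon, dt = 0.25)
    elimination_decomposition(sim)
  }
  dp <- run("non_expressor_star3_star3")
  de <- run("expressor")
  w <- nonexpressor_frequency
  mix <- function(f) w * dp[[f]] + (1 - w) * de[[f]]
  structure(list(fm_cyp3a = mix("fm_cyp3a"), fe_total = mix("fe_total"),
                 fe_pgp = mix("fe_pgp"),
                 fe_renal_filtration = mix("fe_renal_filtration"),
                 fe_unassigned = mix("fe_unassigned"),
                 fraction_of_dose_eliminated =
                   mix("fraction_of_dose_eliminated"),
                 extrapolation_flag = dp$extrapolation_flag ||
                   de$extrapolation_flag),
            class = "elimination_decomposition",
            by_genotype = list(poor = dp, extensive = de))
}
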