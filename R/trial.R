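# Population trial scenarios: genotype stratification, DDI runs with and
# without perpetrators, the EMA-style IC50 sensitivity sweep, and the
# static DDI risk screen.

default_sampling <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 36, 48, 72, 96)

#' Load a scenario configuration
#'
#' Scenario YAML files (see `inst/extdata/scenarios/`) bundle a victim
#' compound, dose regimen, population specification, optional perpetrators,
#' genotype override, IC50 sensitivity divisor, sampling schedule and LLOQ.
#'
#' @param path Path to a scenario YAML file.
#' @return A `scenario` object.
#' @export
load_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  pop <- cfg$population %||% list()
  spec <- population_spec(
    n_trials = pop$n_trials %||% 5,
    n_subjects_per_trial = pop$n_subjects_per_trial %||% 5,
    age_range = unlist(pop$age_range %||% c(20, 90)),
    proportion_female = pop$proportion_female %||% 0.47,
    cyp3a5_nonexpressor_frequency = pop$cyp3a5_nonexpressor_frequency %||% 0.83,
    seed = pop$seed %||% 1L,
    iiv_cv = pop$iiv_cv %||% 0.30)
  reg <- cfg$victim_regimen %||% list()
  regimen <- dose_regimen(reg$route %||% "iv_infusion", reg$amount %||% 2,
                          reg$infusion_duration %||% 0.25,
                          reg$interval, reg$n_doses %||% 1)
  structure(list(
    name = cfg$name %||% basename(path),
    victim = cfg$victim %||% "vincristine",
    victim_regimen = regimen,
    perpetrators = cfg$perpetrators %||% list(),
    genotype_override = cfg$genotype_override %||% "none",
    ic50_divisor = cfg$ic50_divisor %||% 1,
    population = spec,
    use_reference_subject = isTRUE(cfg$use_reference_subject),
    horizon = cfg$horizon %||% 96,
    sampling_times = unlist(cfg$sampling_times %||% default_sampling),
    lloq = cfg$lloq %||% 0.1,
    sites = unlist(cfg$sites %||% "plasma"),
    renal_filtration = isTRUE(cfg$renal_filtration)
  ), class = "scenario")
}

#' Named scenarios shipped with the package
#'
#' `baseline_poor`, `baseline_extensive`, `baseline_population`,
#' `ddi_ibrutinib_plasma`, `ddi_ibrutinib_muscle`,
#' `ddi_acalabrutinib_muscle`, `itraconazole_verification` and
#' `sensitivity_30x`, each mapping to a bundled YAML file.
#'
#' @param name Scenario name.
#' @return A `scenario` object.
#' @export
named_scenario <- function(name) {
  load_scenario(vincpbpk_file("scenarios", paste0(name, ".yaml")))
}

load_bundled_compound <- function(name) {
  load_compound(vincpbpk_file("compounds", paste0(name, ".yaml")))
}

scenario_perpetrators <- function(scenario) {
  lapply(scenario$perpetrators, function(p) {
    cmpd <- load_bundled_compound(p$name %||% p)
    reg <- if (is.list(p) && !is.null(p$amount)) {
      dose_regimen("oral", p$amount, interval = p$interval %||% 24,
                   n_doses = p$n_doses %||% 7, lead_in = p$lead_in %||% 168)
    } else NULL
    list(compound = cmpd, regimen = reg)
  })
}

scenario_subjects <- function(scenario, seed) {
  if (scenario$use_reference_subject) {
    genotype <- if (scenario$genotype_override == "all_extensive")
      "expressor" else "non_expressor_star3_star3"
    return(list(reference_subject(genotype)))
  }
  spec <- scenario$population
  spec$seed <- as.integer(seed)
  sample_population(spec, genotype_override = scenario$genotype_override)
}

muscle_auc24 <- function(sim) {
  auc_trapezoid(sim$time, sim$conc[, "muscle_tissue"], 0,
                min(24, max(sim$time)))
}

#' Run a trial scenario
#'
#' Samples the virtual population (deterministically from `seed`), builds
#' and simulates every subject with and - when perpetrators are configured -
#' without the perpetrator(s), computes clinical-style NCA on the sampling
#' schedule (LLOQ-censored) plus dense muscle-tissue exposure, and pools
#' the results.
#'
#' @param scenario A `scenario` from [load_scenario()] / [named_scenario()].
#' @param seed Integer seed for the population draw.
#' @return A `trial_summary`: per-subject table, pooled means/SDs, and
#'   paired [ddi_ratios()] summaries per requested site.
#' @export
run_scenario <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "scenario"))
  victim <- load_bundled_compound(scenario$victim)
  perps <- scenario_perpetrators(scenario)
  subjects <- scenario_subjects(scenario, seed)
  opts <- model_options(sensitivity_divisor = scenario$ic50_divisor,
                        renal_filtration = scenario$renal_filtration)
  want_muscle <- "muscle" %in% scenario$sites

  rows <- list(); nca_ref <- list(); nca_ddi <- list()
  mus_ref <- list(); mus_ddi <- list()
  for (s in subjects) {
    part <- calibrate_kp_scalar(predict_kp(victim, s$physiology),
                                victim$vss_target, victim, s$physiology)
    base_model <- pbpk_model(s, victim, partitions = part,
                             dosing = scenario$victim_regimen, options = opts)
    sim0 <- tryCatch(simulate_pbpk(base_model, horizon = scenario$horizon),
                     error = function(e)
                       stop_domain("subject %d simulation failed: %s",
                                   s$id, conditionMessage(e)))
    n0 <- nca_from_sim(sim0, times = scenario$sampling_times,
                       lloq = scenario$lloq)
    nca_ref[[length(nca_ref) + 1]] <- n0
    if (want_muscle) mus_ref[[length(mus_ref) + 1]] <-
      list(auc_0_24 = muscle_auc24(sim0),
           cmax = max(sim0$conc[, "muscle_tissue"]))
    if (length(perps)) {
      ddi_model <- pbpk_model(s, victim, perpetrators = perps,
                              partitions = part,
                              dosing = scenario$victim_regimen, options = opts)
      sim1 <- simulate_pbpk(ddi_model, horizon = scenario$horizon)
      n1 <- nca_from_sim(sim1, times = scenario$sampling_times,
                         lloq = scenario$lloq)
      nca_ddi[[length(nca_ddi) + 1]] <- n1
      if (want_muscle) mus_ddi[[length(mus_ddi) + 1]] <-
        list(auc_0_24 = muscle_auc24(sim1),
             cmax = max(sim1$conc[, "muscle_tissue"]))
    }
    rows[[length(rows) + 1]] <- data.frame(
      id = s$id, trial = s$trial, genotype = s$cyp3a5_genotype,
      body_weight = s$body_weight,
      auc_0_inf = n0$auc_0_inf, auc_0_24 = n0$auc_0_24, cmax = n0$cmax,
      half_life = n0$half_life, cl_ml_min = n0$cl, vd = n0$vd)
  }
  per_subject <- do.call(rbind, rows)
  pool <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
      median = median(v))
  }
  pooled <- rbind(auc_0_inf = pool(per_subject$auc_0_inf),
                  auc_0_24 = pool(per_subject$auc_0_24),
                  cmax = pool(per_subject$cmax),
                  half_life = pool(per_subject$half_life),
                  cl_ml_min = pool(per_subject$cl_ml_min),
                  vd = pool(per_subject$vd))
  ddi <- list()
  if (length(perps)) {
    if ("plasma" %in% scenario$sites)
      ddi$plasma <- ddi_ratios(nca_ddi, nca_ref, site = "plasma")
    if (want_muscle)
      ddi$muscle <- ddi_ratios(mus_ddi, mus_ref, site = "muscle")
  }
  structure(list(scenario = scenario$name, seed = as.integer(seed),
                 per_subject = per_subject, pooled = pooled, ddi = ddi,
                 muscle_ref = if (want_muscle)
                   vapply(mus_ref, `[[`, numeric(1), "auc_0_24") else NULL,
                 muscle_ddi = if (want_muscle && length(perps))
                   vapply(mus_ddi, `[[`, numeric(1), "auc_0_24") else NULL,
                 manifest = list(package_version =
                                   as.character(utils::packageVersion("vincpbpk")),
                                 seed = as.integer(seed),
                                 ic50_divisor = scenario$ic50_divisor)),
            class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("<trial_summary> %s (seed %d, n = %d)\n", x$scenario, x$seed,
              nrow(x$per_subject)))
  print(round(x$pooled, 3))
  for (site in names(x$ddi)) print(x$ddi[[site]])
  invisible(x)
}

#' Static regulatory DDI risk screen
#'
#' Basic static criteria for an orally dosed P-gp inhibitor: theoretical
#' gut concentration `I_gut = dose / 0.25 L` (in uM) flagged when
#' `I_gut / IC50 >= 10`, and systemic unbound Cmax (from the steady-state
#' perpetrator profile) flagged when `Cmax,u / IC50 >= 0.1`.  Cut-offs and
#' the 250-mL gut volume follow current regulatory static guidance and are
#' exposed as arguments.
#'
#' @param perpetrator A perpetrator `compound_record`.
#' @param dose Oral dose in mg (default: the compound's default regimen).
#' @param target An inhibition spec of the perpetrator (default: its first
#'   P-gp entry).
#' @param gut_volume_l Gut fluid volume (L).
#' @param gut_cutoff,systemic_cutoff Flagging thresholds.
#' @return A `static_ddi_report` with `i_gut`, `i_max_u` (uM),
#'   `ratio_gut`, `ratio_systemic` and `flags`.
#' @export
static_ddi_screen <- function(perpetrator, dose = NULL, target = NULL,
                              gut_volume_l = 0.25, gut_cutoff = 10,
                              systemic_cutoff = 0.1) {
  if (is.null(target)) {
    for (sp in perpetrator$inhibition %||% list())
      if (sp$target == "P-gp") { target <- sp; break }
    if (is.null(target)) stop_domain("no P-gp inhibition spec for '%s'",
                                     perpetrator$name)
  }
  reg <- perpetrator$absorption$dose_regimen_default
  dose <- dose %||% reg$amount
  check_scalar(dose, "dose", 0, Inf, lower_open = TRUE)
  oral <- perpetrator$route == "oral"
  i_gut <- if (oral) dose / gut_volume_l / perpetrator$molecular_weight * 1000
           else NA_real_
  regimen <- dose_regimen("oral", dose, interval = reg$interval %||% 24)
  cmax_tot <- if (oral) {
    prof <- perpetrator_plasma_profile(perpetrator, regimen)
    max(prof(seq(0, regimen$interval, by = 0.05)))
  } else NA_real_
  i_max_u <- perpetrator$fu_plasma * cmax_tot / perpetrator$molecular_weight
  ratio_gut <- i_gut / target$ic50
  ratio_sys <- i_max_u / target$ic50
  flags <- character()
  if (oral && is.finite(ratio_gut) && ratio_gut >= gut_cutoff)
    flags <- c(flags, "gut_pgp_inhibition_risk")
  if (is.finite(ratio_sys) && ratio_sys >= systemic_cutoff)
    flags <- c(flags, "systemic_pgp_inhibition_risk")
  structure(list(perpetrator = perpetrator$name, dose = dose,
                 i_gut = i_gut, i_max_u = i_max_u,
                 ratio_gut = ratio_gut, ratio_systemic = ratio_sys,
                 gut_applicable = oral, flags = flags),
            class = "static_ddi_report")
}

#' @export
print.static_ddi_report <- function(x, ...) {
  cat(sprintf("<static_ddi_report> %s %g mg\n", x$perpetrator, x$dose))
  cat(sprintf("  I_gut %.4g uM (ratio %.3g)%s\n", x$i_gut, x$ratio_gut,
              if (!x$gut_applicable) " [not applicable]" else ""))
  cat(sprintf("  Cmax,u %.4g uM (ratio %.3g)\n", x$i_max_u, x$ratio_systemic))
  cat("  flags:", if (length(x$flags)) paste(x$flags, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' IC50 sensitivity sweep
#'
#' Re-runs a DDI scenario across a set of P-gp IC50 divisors (the EMA-style
#' sensitivity analysis uses divisor 30) and tabulates the DDI summaries
#' per site.
#'
#' @param scenario A DDI `scenario`.
#' @param divisors Numeric vector of divisors (>= 1).
#' @param seed Population seed.
#' @return A data frame with one row per divisor x site: AUC and Cmax
#'   ratio geometric means; for muscle also the absolute with/without AUCs.
#' @export
sensitivity_sweep <- function(scenario, divisors = c(1, 30), seed = 1L) {
  if (any(divisors < 1)) stop_domain("divisors must be >= 1")
  out <- list()
  for (d in divisors) {
    sc <- scenario
    sc$ic50_divisor <- d
    res <- run_scenario(sc, seed = seed)
    for (site in names(res$ddi)) {
      s <- res$ddi[[site]]
      out[[length(out) + 1]] <- data.frame(
        divisor = d, site = site,
        auc_ratio = s$auc_ratio, cmax_ratio = s$cmax_ratio,
        muscle_auc_with = if (site == "muscle")
          mean(res$muscle_ddi) else NA_real_,
        muscle_auc_without = if (site == "muscle")
          mean(res$muscle_ref) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Pathway-wise DDI attribution
#'
#' Decomposes a perpetrator's effect on victim exposure into its P-gp and
#' CYP3A4/5 inhibition components by re-running the interaction with only
#' one target class active at a time (used for the itraconazole
#' verification scenario).
#'
#' @param scenario A DDI `scenario` with one perpetrator.
#' @param seed Population seed.
#' @return A data frame with AUC ratios for the full interaction, the
#'   P-gp-only component and the CYP3A-only component.
#' @export
ddi_pathway_attribution <- function(scenario, seed = 1L) {
  stopifnot(length(scenario$perpetrators) == 1)
  filter_targets <- function(keep) {
    function(cmpd) {
      cmpd$inhibition <- Filter(function(sp)
        (sp$target == "P-gp") == keep, cmpd$inhibition)
      cmpd
    }
  }
  run_with <- function(fltr) {
    sc <- scenario
    res <- run_scenario_filtered(sc, seed, fltr)
    res$ddi$plasma$auc_ratio
  }
  full <- run_scenario(scenario, seed = seed)$ddi$plasma$auc_ratio
  pgp_only <- run_with(filter_targets(TRUE))
  cyp_only <- run_with(filter_targets(FALSE))
  data.frame(component = c("full", "pgp_only", "cyp3a_only"),
             auc_ratio = c(full, pgp_only, cyp_only))
}

run_scenario_filtered <- function(scenario, seed, compound_filter) {
  old <- scenario$perpetrators
  perps <- scenario_perpetrators(scenario)
  perps <- lapply(perps, function(p) {
    p$compound <- compound_filter(p$compound)
    p
  })
  # temporary scenario with pre-resolved perpetrators
  victim <- load_bundled_compound(scenario$victim)
  subjects <- scenario_subjects(scenario, seed)
  opts <- model_options(sensitivity_divisor = scenario$ic50_divisor)
  nca_ref <- list(); nca_ddi <- list()
  for (s in subjects) {
    part <- calibrate_kp_scalar(predict_kp(victim, s$physiology),
                                victim$vss_target, victim, s$physiology)
    sim0 <- simulate_pbpk(pbpk_model(s, victim, partitions = part,
                                     dosing = scenario$victim_regimen,
                                     options = opts),
                          horizon = scenario$horizon)
    sim1 <- simulate_pbpk(pbpk_model(s, victim, perpetrators = perps,
                                     partitions = part,
                                     dosing = scenario$victim_regimen,
                                     options = opts),
                          horizon = scenario$horizon)
    nca_ref[[length(nca_ref) + 1]] <-
      nca_from_sim(sim0, times = scenario$sampling_times, lloq = scenario$lloq)
    nca_ddi[[length(nca_ddi) + 1]] <-
      nca_from_sim(sim1, times = scenario$sampling_times, lloq = scenario$lloq)
  }
  list(ddi = list(plasma = ddi_ratios(nca_ddi, nca_ref, site = "plasma")))
}
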