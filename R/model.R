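# Assembly of the whole-body PBPK model: perfusion-limited organs,
# permeability-limited liver/kidney and the duplicated permeability-limited
# muscle organ, saturable metabolism and P-gp efflux, and competitive
# inhibition links to co-dosed perpetrators.

#' Dose regimen
#'
#' @param route `"iv_infusion"` or `"oral"`.
#' @param amount Dose in mg (> 0).
#' @param infusion_duration Infusion duration in h (iv only; e.g. 0.25 for
#'   the 2 mg / 15 min vincristine regimen).
#' @param interval Dosing interval in h for repeated dosing (e.g. 24 for QD,
#'   12 for BID).
#' @param n_doses Number of doses.
#' @param lead_in Perpetrator pre-dosing duration in h before the victim
#'   dose (used to reach steady state; default 0).
#' @return A `dose_regimen` list.
#' @export
dose_regimen <- function(route = c("iv_infusion", "oral"), amount,
                         infusion_duration = NULL, interval = NULL,
                         n_doses = 1, lead_in = 0) {
  route <- match.arg(route)
  check_scalar(amount, "amount", 0, Inf, lower_open = TRUE)
  if (route == "iv_infusion") {
    if (is.null(infusion_duration))
      stop_domain("iv_infusion regimens need an infusion_duration")
    check_scalar(infusion_duration, "infusion_duration", 0, Inf, lower_open = TRUE)
  }
  structure(list(route = route, amount = amount,
                 infusion_duration = infusion_duration,
                 interval = interval, n_doses = n_doses, lead_in = lead_in),
            class = "dose_regimen")
}

#' Model options
#'
#' @param renal_filtration Include glomerular filtration (fu x GFR) as an
#'   additional renal pathway.  Default `FALSE`: the kidney model is P-gp
#'   secretion only, matching the derivation of renal clearance from
#'   transporter kinetics (net tubular reabsorption of the filtered load is
#'   assumed; switch on to add fu x GFR).
#' @param muscle_duplicate Add the permeability-limited muscle organ while
#'   retaining the perfusion muscle compartment (the duplication is
#'   deliberate; muscle exposure outputs are read from the
#'   permeability-limited organ).  Muscle blood flow is split evenly between
#'   the two muscle compartments so venous returns still sum to cardiac
#'   output.
#' @param sensitivity_divisor Divisor applied to every perpetrator P-gp IC50
#'   (1 = measured values; 30 = the EMA-style sensitivity analysis).
#' @param cyp3a5_expression_ratio Optional extra multiplier on the
#'   extensive-expressor CYP3A5 Vmax (default 1: the per-genotype enzyme
#'   kinetics are used exactly as parameterized).
#' @param rtol,atol Solver tolerances (stiff integrator).
#' @param dt_report Reporting grid step in h.
#' @return A `model_options` list.
#' @export
model_options <- function(renal_filtration = FALSE, muscle_duplicate = TRUE,
                          sensitivity_divisor = 1,
                          cyp3a5_expression_ratio = 1,
                          rtol = 1e-8, atol = 1e-10, dt_report = 0.05) {
  check_scalar(sensitivity_divisor, "sensitivity_divisor", 1)
  check_scalar(cyp3a5_expression_ratio, "cyp3a5_expression_ratio", 0,
               Inf, lower_open = TRUE)
  structure(list(renal_filtration = renal_filtration,
                 muscle_duplicate = muscle_duplicate,
                 sensitivity_divisor = sensitivity_divisor,
                 cyp3a5_expression_ratio = cyp3a5_expression_ratio,
                 rtol = rtol, atol = atol, dt_report = dt_report),
            class = "model_options")
}

.perf_organs <- c("adipose", "bone", "brain", "gut", "heart", "skin",
                  "spleen", "pancreas", "muscle", "rest")
.portal_organs <- c("gut", "spleen", "pancreas")

select_enzyme_kinetics <- function(victim, genotype) {
  wanted_class <- if (genotype == "expressor") "extensive" else "poor"
  out <- list()
  for (ek in victim$enzyme_kinetics %||% list()) {
    if (ek$enzyme == "CYP3A4") out[[length(out) + 1]] <- ek
    if (ek$enzyme == "CYP3A5" && identical(ek$expressor_class, wanted_class))
      out[[length(out) + 1]] <- ek
  }
  out
}

transporter_for_organ <- function(victim, organ) {
  for (tk in victim$transporter_kinetics %||% list())
    if (tk$organ == organ) return(tk)
  NULL
}

pl_organ_pars <- function(victim, phys, organ, options) {
  pp <- victim$permeability[[organ]]
  if (is.null(pp)) return(NULL)
  row <- organ_row(phys, organ)
  mw <- victim$molecular_weight
  bw_scale <- phys$body_weight / 70
  n_million <- if (!is.null(pp$cells_per_g)) {
    pp$cells_per_g * row$volume * 1000        # volume L ~ kg -> g
  } else if (!is.null(pp$cells_million)) {
    pp$cells_million * bw_scale
  } else stop_domain("permeability$%s needs cells_per_g or cells_million", organ)
  ps_pd <- pp$cl_pd * n_million * 60e-6 * (pp$ps_scalar %||% 1)   # L/h
  tk <- transporter_for_organ(victim, organ)
  jmax <- 0; km_pgp <- 1
  if (!is.null(tk)) {
    jmax <- tk$j_max * n_million * (tk$raf_ref %||% 1) *
      (pp$pgp_scalar %||% 1) * 60e-6 * mw                         # ug/h
    km_pgp <- tk$k_m * mw                                         # ug/L
  }
  q <- row$flow
  if (organ == "muscle") q <- q * 0.5   # flow split with the retained
                                        # perfusion muscle compartment
  list(organ = organ,
       v_vasc = row$vasc_frac * row$volume,
       v_ew = row$f_ew * row$volume,
       v_iw = row$f_iw * row$volume,
       v_total = row$volume,
       q = q,
       ps_vasc = (pp$vasc_ps_per_flow %||% 2) * q,
       ps_pd = ps_pd,
       fu_ew = pp$fu_ew,
       fu_iw_eff = pp$fu_iw / (pp$iw_binding %||% 1),
       jmax = jmax, km_pgp = km_pgp)
}

#' Build a whole-body PBPK model for one subject
#'
#' Assembles the compartment graph: perfusion-limited organs with calibrated
#' Kp values; three-zone (vascular / extracellular water / intracellular
#' water) liver, kidney and duplicated muscle; CYP3A4 + CYP3A5 saturable
#' metabolism in the liver intracellular zone (genotype branch selected from
#' the subject's CYP3A5 status); saturable P-gp efflux from the
#' intracellular zone to bile (liver), urine (kidney) or extracellular water
#' (muscle); a first-order unassigned systemic clearance from venous blood;
#' and dynamic competitive-inhibition links for each perpetrator.
#'
#' @param subject A `subject` ([reference_subject()] or an element of
#'   [sample_population()]).
#' @param victim A `compound_record` for the victim drug.
#' @param perpetrators List of perpetrator specifications, each a list with
#'   elements `compound` (a `compound_record`) and `regimen` (a
#'   [dose_regimen()]); the compound's default regimen is used when
#'   `regimen` is absent.
#' @param partitions A calibrated `partition_set` for the victim.
#' @param dosing A [dose_regimen()] for the victim (default: 2 mg IV over
#'   15 min).
#' @param options A [model_options()].
#' @return An object of class `pbpk_model`.
#' @export
pbpk_model <- function(subject, victim, perpetrators = list(),
                       partitions, dosing = dose_regimen("iv_infusion", 2, 0.25),
                       options = model_options()) {
  stopifnot(inherits(subject, "subject"), inherits(victim, "compound_record"),
            inherits(partitions, "partition_set"))
  phys <- subject$physiology
  mw <- victim$molecular_weight

  for (org in names(victim$permeability %||% list()))
    organ_row(phys, org)  # errors if an organ is missing from physiology

  eks <- select_enzyme_kinetics(victim, subject$cyp3a5_genotype)
  if (subject$cyp3a5_genotype == "expressor" &&
      length(victim$enzyme_kinetics %||% list()) &&
      !any(vapply(eks, function(e) e$enzyme == "CYP3A5", logical(1))) &&
      any(vapply(victim$enzyme_kinetics, function(e) e$enzyme == "CYP3A5",
                 logical(1))))
    stop_domain("no extensive-expressor CYP3A5 kinetics for expressor subject")

  liver_g <- organ_row(phys, "liver")$volume * 1000
  enz <- lapply(eks, function(ek) {
    vmax <- ek$v_max * (ek$abundance %||% 1) * phys$mppgl * liver_g *
      60e-6 * mw * subject$multipliers$cyp3a                                  # ug/h
    if (ek$enzyme == "CYP3A5" && identical(ek$expressor_class, "extensive"))
      vmax <- vmax * options$cyp3a5_expression_ratio
    list(enzyme = ek$enzyme, vmax = vmax,
         km_u = ek$k_m * (victim$fu_mic %||% 1) * mw)            # ug/L
  })

  pl <- list(liver = pl_organ_pars(victim, phys, "liver", options),
             kidney = pl_organ_pars(victim, phys, "kidney", options),
             muscle = if (options$muscle_duplicate)
               pl_organ_pars(victim, phys, "muscle", options) else NULL)
  for (nm in names(pl)) {
    if (!is.null(pl[[nm]]) && pl[[nm]]$jmax > 0)
      pl[[nm]]$jmax <- pl[[nm]]$jmax * subject$multipliers$pgp
  }

  # interaction links: perpetrator x target x site, with effective Ki (uM)
  perps <- lapply(perpetrators, function(p) {
    if (is.null(p$regimen)) {
      dr <- p$compound$absorption$dose_regimen_default
      p$regimen <- dose_regimen(dr$route, dr$amount, dr$infusion_duration,
                                dr$interval, dr$n_doses %||% 1, dr$lead_in %||% 0)
    }
    p
  })
  links <- list()
  victim_targets <- c(
    if (length(enz)) vapply(enz, `[[`, character(1), "enzyme"),
    if (any(vapply(pl, function(o) !is.null(o) && o$jmax > 0, logical(1)))) "P-gp")
  for (p in perps) {
    specs <- p$compound$inhibition %||% list()
    # one spec per target: the most potent (lowest IC50) assay result,
    # matching the convention of dividing "the lowest of the original
    # input values" in the sensitivity analysis
    tgts <- unique(vapply(specs, `[[`, character(1), "target"))
    specs <- lapply(tgts, function(tg) {
      cand <- Filter(function(s) s$target == tg, specs)
      cand[[which.min(vapply(cand, `[[`, numeric(1), "ic50"))]]
    })
    for (spec in specs) {
      if (!spec$target %in% victim_targets) next
      div <- if (spec$target == "P-gp") options$sensitivity_divisor else 1
      ki <- effective_ki(spec, sensitivity_divisor =
                           max(div, spec$sensitivity_divisor %||% 1))
      sites <- if (spec$target == "P-gp") {
        c("liver", "kidney", "muscle")
      } else "liver"
      for (site in sites)
        links[[length(links) + 1]] <- list(
          perpetrator = p$compound$name, target = spec$target,
          site = site, ki = ki)
    }
  }

  structure(list(
    subject = subject, victim = victim, perpetrators = perps,
    partitions = partitions, dosing = dosing, options = options,
    enzymes = enz, pl = pl, interaction_links = links
  ), class = "pbpk_model")
}

#' @rdname pbpk_model
#' @export
build_model <- pbpk_model

#' Activate dynamic-inhibition links of a model
#'
#' Precomputes, for every interaction site, the time course of the unbound
#' perpetrator concentration (from the closed-form steady-state perpetrator
#' profile and its site-enrichment factors) and the resulting competitive
#' scaling factor `1 + sum_p Iu_p(t)/Ki_p` applied to the victim's P-gp and
#' CYP3A Km values at that site.  [pbpk_model()] calls this lazily during
#' simulation; it is exported so the inhibition time courses can be
#' inspected.
#'
#' @param model A `pbpk_model`.
#' @return The model with an `inhibition_factors` element: list of functions
#'   of time (h since victim dose) returning the Km scaling factor per
#'   target/site.
#' @export
apply_dynamic_inhibition <- function(model) {
  stopifnot(inherits(model, "pbpk_model"))
  sites <- list()   # key "target|site" -> list of (iu_fun, ki)
  for (link in model$interaction_links) {
    p <- NULL
    for (cand in model$perpetrators)
      if (cand$compound$name == link$perpetrator) p <- cand
    if (is.null(p)) stop_domain("no perpetrator regimen for '%s'", link$perpetrator)
    iu <- perpetrator_site_unbound(p$compound, p$regimen, link$site)
    key <- paste(link$target, link$site, sep = "|")
    sites[[key]] <- c(sites[[key]], list(list(iu = iu, ki = link$ki)))
  }
  model$inhibition_factors <- lapply(sites, function(terms) {
    function(t) {
      f <- 1
      for (tm in terms) f <- f + tm$iu(t) / tm$ki
      f
    }
  })
  model
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> victim %s, subject %.0f kg (%s CYP3A5)\n",
              x$victim$name, x$subject$body_weight,
              if (x$subject$cyp3a5_genotype == "expressor") "extensive" else "poor"))
  cat(sprintf("  dosing: %s %g mg%s\n", x$dosing$route, x$dosing$amount,
              if (x$dosing$route == "iv_infusion")
                sprintf(" over %g h", x$dosing$infusion_duration) else ""))
  if (length(x$perpetrators))
    cat("  perpetrators:",
        paste(vapply(x$perpetrators, function(p) p$compound$name,
                     character(1)), collapse = ", "), "\n")
  cat(sprintf("  interaction links: %d; sensitivity divisor %g\n",
              length(x$interaction_links), x$options$sensitivity_divisor))
  invisible(x)
}
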