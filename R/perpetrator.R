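# Simplified perpetrator pharmacokinetics.
#
# Perpetrators (orally dosed inhibitors at steady state) are represented by
# a one-compartment first-order absorption model parameterized with
# published clinical PK constants (CL/F, V/F, ka) from their compound
# files.  Because the perpetrator is unaffected by the victim, its plasma
# profile has a closed-form superposition solution, which is evaluated
# directly instead of co-integrating ODEs.  Site concentrations driving
# inhibition are unbound plasma times a documented site-enrichment factor.

#' Steady-state plasma concentration of an orally dosed perpetrator
#'
#' Closed-form superposition of a one-compartment first-order absorption
#' model at steady state: for time `t` within the dosing interval `tau`,
#' `C(t) = F D ka / (V (ka - k)) * (exp(-k t)/(1 - exp(-k tau)) -
#' exp(-ka t)/(1 - exp(-ka tau)))`.  The victim dose is taken at a
#' perpetrator dosing time, so `t` is interpreted modulo `tau`; the
#' regimen's `lead_in` records the pre-dosing used to justify steady state.
#'
#' @param compound Perpetrator `compound_record` with a `disposition` block
#'   (`cl_f` L/h, `v_f` L) and an `absorption` block (`ka` 1/h, `f_abs`).
#' @param regimen A [dose_regimen()] with `route = "oral"`, `amount` (mg)
#'   and `interval` (h).
#' @return A vectorized function of time (h) returning total plasma
#'   concentration in ng/mL; the zero function if the dose is zero.
#' @export
perpetrator_plasma_profile <- function(compound, regimen) {
  if (regimen$route != "oral")
    stop_domain("perpetrator profiles are defined for oral regimens")
  d <- compound$disposition
  if (is.null(d)) stop_domain("perpetrator '%s' lacks a disposition block",
                              compound$name)
  dose_ug <- regimen$amount * 1000 * (compound$absorption$f_abs %||% 1)
  if (dose_ug == 0) return(function(t) rep(0, length(t)))
  ka <- compound$absorption$ka
  k <- d$cl_f / d$v_f
  if (abs(ka - k) < 1e-9) ka <- k * (1 + 1e-6)
  tau <- regimen$interval %||% 24
  v <- d$v_f
  function(t) {
    ts <- t %% tau
    a <- dose_ug * ka / (v * (ka - k))
    c_ng <- a * (exp(-k * ts) / (1 - exp(-k * tau)) -
                   exp(-ka * ts) / (1 - exp(-ka * tau)))
    pmax(c_ng, 0)
  }
}

#' Unbound perpetrator concentration at an interaction site
#'
#' Unbound plasma concentration (fu x total plasma) times the compound's
#' site-enrichment factor, converted to uM.  Sites: `liver` and `muscle`
#' use the respective intracellular-water enrichment; `kidney` uses unbound
#' plasma (no proximal-tubule model; enrichment 1 unless configured).
#'
#' @inheritParams perpetrator_plasma_profile
#' @param site `"liver"`, `"kidney"` or `"muscle"`.
#' @return A function of time returning unbound site concentration in uM.
#' @export
perpetrator_site_unbound <- function(compound, regimen, site) {
  cp <- perpetrator_plasma_profile(compound, regimen)
  enrich <- (compound$site_enrichment %||% list())[[site]] %||% 1
  fu <- compound$fu_plasma
  mw <- compound$molecular_weight
  function(t) fu * enrich * cp(t) / mw
}
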