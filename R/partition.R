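# Tissue-to-plasma partition coefficients (Rodgers & Rowland mechanistic
# method) and calibration of a global Kp scalar to an observed steady-state
# volume of distribution.

ionization_factor <- function(compound_class, pka, ph) {
  switch(compound_class,
    monoprotic_acid = 1 + 10^(ph - pka),
    monoprotic_base = 1 + 10^(pka - ph),
    neutral = rep(1, length(ph)),
    stop_domain("unsupported compound class '%s'", compound_class))
}

#' Fraction ionized at a given pH (Henderson-Hasselbalch)
#'
#' For a monoprotic acid with pKa 5.15 at plasma pH 7.4 this is
#' 1/(1+10^(5.15-7.4)) = 0.9944.
#'
#' @param compound A `compound_record` (class and pKa are used).
#' @param ph pH (default plasma 7.4).
#' @return Fraction of the compound in the ionized form.
#' @export
fraction_ionized <- function(compound, ph = 7.4) {
  cls <- compound$compound_class %||% "neutral"
  if (cls == "neutral") return(0)
  x <- ionization_factor(cls, compound$pka, ph)
  1 - 1 / x
}

#' Predict tissue-to-plasma partition coefficients
#'
#' Mechanistic Rodgers & Rowland partitioning for acids, neutrals and
#' monoprotic bases treated through neutral-lipid/phospholipid partitioning
#' plus albumin-type protein binding, using the tissue composition shipped
#' with the physiology table.  Returns unscaled coefficients
#' (`kp_scalar = 1`); see [calibrate_kp_scalar()].
#'
#' @param compound A `compound_record` with `log_p`, `compound_class`,
#'   `pka`, `blood_to_plasma` and `fu_plasma`.
#' @param physiology A [reference_physiology()] object.
#' @return An object of class `partition_set`: per-organ Kp (tissue:plasma),
#'   the scalar, and the predicted Vss in L/kg.
#' @export
predict_kp <- function(compound, physiology) {
  stopifnot(inherits(compound, "compound_record"),
            inherits(physiology, "system_physiology"))
  org <- physiology$organs
  if (any(is.na(org$f_ew)))
    stop_domain("tissue composition missing for organ(s): %s",
                paste(org$organ[is.na(org$f_ew)], collapse = ", "))
  P <- 10^(compound$log_p %||% 0)
  fu <- compound$fu_plasma
  cls <- compound$compound_class %||% "neutral"
  pka <- compound$pka %||% NA_real_
  ph <- physiology$ph
  Y <- ionization_factor(cls, pka, ph$plasma)    # plasma
  X <- ionization_factor(cls, pka, ph$iw)        # intracellular water
  E <- ionization_factor(cls, pka, ph$ew)        # extracellular water

  lipid <- function(f_nl, f_npl) (P * f_nl + (0.3 * P + 0.7) * f_npl) / Y
  lipid_p <- lipid(physiology$plasma_f_nl, physiology$plasma_f_npl)
  prot_p <- 1 / fu - 1 - lipid_p                 # albumin-class binding in plasma
  kpu <- org$f_ew * (E / Y) + org$f_iw * (X / Y) +
    lipid(org$f_nl, org$f_npl) + prot_p * org$alb_ratio
  kp <- kpu * fu
  names(kp) <- org$organ
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop_domain("non-positive or non-finite Kp predicted; check inputs")
  ps <- structure(list(kp = kp, kp_scalar = 1, method = "rodgers_rowland_2",
                       compound = compound$name), class = "partition_set")
  ps$vss_predicted <- vss_from_partitions(ps, compound, physiology)
  ps
}

#' Steady-state volume of distribution from a partition set
#'
#' `Vss = Vplasma + Verythrocyte * E:P + sum(Vt * Kp * scalar)` in L/kg,
#' with the erythrocyte:plasma ratio derived from B/P and hematocrit.
#'
#' @param partitions A `partition_set`.
#' @param compound A `compound_record`.
#' @param physiology A [reference_physiology()] object.
#' @return Vss in L/kg body weight.
#' @export
vss_from_partitions <- function(partitions, compound, physiology) {
  hct <- physiology$hematocrit
  ep <- (compound$blood_to_plasma - (1 - hct)) / hct
  v_pl <- physiology$v_blood * (1 - hct)
  v_rbc <- physiology$v_blood * hct
  vt <- sum(physiology$organs$volume * partitions$kp * partitions$kp_scalar)
  (v_pl + v_rbc * ep + vt) / physiology$body_weight
}

#' Calibrate the global Kp scalar to a target Vss
#'
#' Applies one multiplicative scalar to every tissue Kp such that the
#' recomputed Vss equals the target (e.g. the observed clinical 1.64 L/kg
#' for vincristine) to machine precision; the solution is closed-form
#' because Vss is affine in the scalar.
#'
#' @param partitions An unscaled `partition_set` from [predict_kp()].
#' @param vss_target Target Vss in L/kg.
#' @param compound A `compound_record`.
#' @param physiology A [reference_physiology()] object.
#' @return The `partition_set` with `kp_scalar` set and `vss_predicted`
#'   equal to the target.
#' @export
calibrate_kp_scalar <- function(partitions, vss_target, compound, physiology) {
  stopifnot(inherits(partitions, "partition_set"))
  check_scalar(vss_target, "vss_target", 0, Inf, lower_open = TRUE)
  hct <- physiology$hematocrit
  ep <- (compound$blood_to_plasma - (1 - hct)) / hct
  bw <- physiology$body_weight
  v_fixed <- physiology$v_blood * (1 - hct) + physiology$v_blood * hct * ep
  vt_unscaled <- sum(physiology$organs$volume * partitions$kp)
  if (vss_target * bw <= v_fixed)
    stop_domain("vss_target %.3g L/kg below the anatomical minimum %.3g L/kg",
                vss_target, v_fixed / bw)
  s <- (vss_target * bw - v_fixed) / vt_unscaled
  partitions$kp_scalar <- s
  partitions$vss_predicted <- vss_from_partitions(partitions, compound, physiology)
  partitions
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> %s (%s), kp_scalar %.4g, Vss %.4g L/kg\n",
              x$compound, x$method, x$kp_scalar, x$vss_predicted))
  print(round(x$kp * x$kp_scalar, 4))
  invisible(x)
}

#' Export a partition set as a data frame
#'
#' @param x A `partition_set`.
#' @param ... Unused.
#' @return A data frame with organ, unscaled and scaled Kp.
#' @export
as.data.frame.partition_set <- function(x, ...) {
  data.frame(organ = names(x$kp), kp_unscaled = as.numeric(x$kp),
             kp = as.numeric(x$kp) * x$kp_scalar, row.names = NULL)
}
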