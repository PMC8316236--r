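# Compound parameter model: loading, validation and small derived quantities.
#
# One YAML file per compound.  Units are fixed by the schema and echoed in a
# `units` block inside each file; unknown keys are rejected so that typos
# fail loudly instead of being silently ignored.

.compound_classes <- c("monoprotic_acid", "monoprotic_base", "neutral")
.enzymes          <- c("CYP3A4", "CYP3A5")
.expressor_classes <- c("extensive", "poor", "n/a")
.transporters     <- "P-gp"
.pl_organs        <- c("liver", "kidney", "muscle")
.inhibition_targets <- c("P-gp", "CYP3A4", "CYP3A5")
.ki_conventions   <- c("ki_equals_ic50", "ki_equals_ic50_over_2")

.compound_keys <- c(
  "schema_version", "name", "provenance", "units",
  "molecular_weight", "log_p", "compound_class", "pka", "blood_to_plasma",
  "fu_plasma", "fu_mic", "vss_target", "renal_cl_observed", "route",
  "absorption", "disposition", "enzyme_kinetics", "transporter_kinetics",
  "permeability", "inhibition", "additional_systemic_cl", "site_enrichment"
)

.permeability_keys <- c("cl_pd", "fu_iw", "fu_ew", "ps_scalar",
                        "cells_per_g", "cells_million", "pgp_scalar",
                        "iw_binding", "vasc_ps_per_flow")

#' Load and validate a compound parameter file
#'
#' Reads a YAML compound file (see `inst/extdata/compounds/`) and returns a
#' validated `compound_record`.  Canonical units: molecular weight g/mol,
#' enzyme Vmax pmol/min/mg microsomal protein, enzyme/transporter Km uM,
#' transporter Jmax pmol/min/million cells, passive diffusion clearance
#' CL_PD uL/min/million cells, clearances L/h, IC50 uM.
#'
#' @param path Path to a compound YAML file.
#' @return An object of class `compound_record`.
#' @examples
#' vcr <- load_compound(vincpbpk_file("compounds", "vincristine.yaml"))
#' vcr$molecular_weight
#' @export
load_compound <- function(path) {
  if (!file.exists(path)) stop_domain("compound file not found: %s", path)
  raw <- yaml::read_yaml(path)
  validate_compound(raw, source = path)
}

#' Validate a compound parameter list
#'
#' @param x A named list with the compound schema fields.
#' @param source Optional label used in error messages.
#' @return The validated `compound_record`.
#' @export
validate_compound <- function(x, source = "<list>") {
  if (!is.list(x)) stop_domain("compound definition must be a list")
  unknown <- setdiff(names(x), .compound_keys)
  if (length(unknown))
    stop_domain("%s: unknown key(s): %s", source, paste(unknown, collapse = ", "))
  req <- c("name", "molecular_weight", "blood_to_plasma", "fu_plasma", "route")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop_domain("%s: missing required field(s): %s", source,
                paste(miss, collapse = ", "))

  check_scalar(x$molecular_weight, "molecular_weight", 0, Inf, lower_open = TRUE)
  check_scalar(x$blood_to_plasma, "blood_to_plasma", 0, Inf, lower_open = TRUE)
  check_scalar(x$fu_plasma, "fu_plasma", 0, 1, lower_open = TRUE)
  if (!is.null(x$fu_mic)) check_scalar(x$fu_mic, "fu_mic", 0, 1, lower_open = TRUE)
  if (!is.null(x$log_p)) check_scalar(x$log_p, "log_p")
  if (!is.null(x$pka)) check_scalar(x$pka, "pka")
  if (!is.null(x$vss_target))
    check_scalar(x$vss_target, "vss_target", 0, Inf, lower_open = TRUE)
  if (!is.null(x$renal_cl_observed))
    check_scalar(x$renal_cl_observed, "renal_cl_observed", 0)
  if (!is.null(x$additional_systemic_cl))
    check_scalar(x$additional_systemic_cl, "additional_systemic_cl", 0)
  if (!is.null(x$compound_class) && !x$compound_class %in% .compound_classes)
    stop_domain("%s: compound_class must be one of %s", source,
                paste(.compound_classes, collapse = ", "))
  if (!x$route %in% c("iv_infusion", "oral"))
    stop_domain("%s: route must be iv_infusion or oral", source)
  if (x$route == "iv_infusion" && !is.null(x$absorption))
    stop_domain("%s: iv compounds must not carry an absorption block", source)
  if (x$route == "oral") {
    if (is.null(x$absorption))
      stop_domain("%s: oral compounds need an absorption block", source)
    check_scalar(x$absorption$ka, "absorption$ka", 0, Inf, lower_open = TRUE)
    check_scalar(x$absorption$f_abs, "absorption$f_abs", 0, 1, lower_open = TRUE)
  }

  for (ek in x$enzyme_kinetics %||% list()) {
    if (!ek$enzyme %in% .enzymes)
      stop_domain("%s: unknown enzyme '%s'", source, ek$enzyme)
    if (!(ek$expressor_class %||% "n/a") %in% .expressor_classes)
      stop_domain("%s: unknown expressor_class '%s'", source, ek$expressor_class)
    check_scalar(ek$v_max, "enzyme v_max", 0)
    check_scalar(ek$k_m, "enzyme k_m", 0, Inf, lower_open = TRUE)
    check_scalar(ek$abundance %||% 1, "enzyme abundance", 0, Inf,
                 lower_open = TRUE)
  }
  for (tk in x$transporter_kinetics %||% list()) {
    if (!tk$transporter %in% .transporters)
      stop_domain("%s: unknown transporter '%s'", source, tk$transporter)
    if (!tk$organ %in% .pl_organs)
      stop_domain("%s: transporter organ '%s' not one of %s", source, tk$organ,
                  paste(.pl_organs, collapse = ", "))
    check_scalar(tk$j_max, "transporter j_max", 0)
    check_scalar(tk$k_m, "transporter k_m", 0, Inf, lower_open = TRUE)
    check_scalar(tk$raf_ref %||% 1, "transporter raf_ref", 0, Inf, lower_open = TRUE)
  }
  for (org in names(x$permeability %||% list())) {
    if (!org %in% .pl_organs)
      stop_domain("%s: permeability organ '%s' not in physiology table", source, org)
    pp <- x$permeability[[org]]
    unknown <- setdiff(names(pp), .permeability_keys)
    if (length(unknown))
      stop_domain("%s: permeability$%s unknown key(s): %s", source, org,
                  paste(unknown, collapse = ", "))
    check_scalar(pp$cl_pd, "cl_pd", 0, Inf, lower_open = TRUE)
    check_scalar(pp$fu_iw, "fu_iw", 0, 1, lower_open = TRUE)
    check_scalar(pp$fu_ew, "fu_ew", 0, 1, lower_open = TRUE)
  }
  for (ih in x$inhibition %||% list()) {
    validate_inhibition_spec(ih, source = source)
  }
  structure(x, class = "compound_record")
}

validate_inhibition_spec <- function(spec, source = "<spec>") {
  if (!spec$target %in% .inhibition_targets)
    stop_domain("%s: inhibition target '%s' unknown", source, spec$target)
  check_scalar(spec$ic50, "ic50", 0, Inf, lower_open = TRUE)
  check_scalar(spec$sensitivity_divisor %||% 1, "sensitivity_divisor", 1)
  if (!(spec$ki_convention %||% "ki_equals_ic50") %in% .ki_conventions)
    stop_domain("%s: unknown ki_convention '%s'", source, spec$ki_convention)
  if (!is.null(spec$assay_system) &&
      !spec$assay_system %in% c("cell_based", "vesicle"))
    stop_domain("%s: unknown assay_system '%s'", source, spec$assay_system)
  invisible(spec)
}

#' Write a compound record back to YAML
#'
#' Numeric fields are serialized at full double precision so that
#' `load_compound(write_compound(x, f))` reproduces them bit-identically.
#'
#' @param record A `compound_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_compound <- function(record, path) {
  stopifnot(inherits(record, "compound_record"))
  txt <- yaml::as.yaml(unclass(record), precision = 17)
  writeLines(txt, path)
  invisible(path)
}

#' Convert a molar concentration to a mass concentration
#'
#' 1 uM of a compound with molecular weight MW g/mol is MW ng/mL.
#'
#' @param c Concentration in uM (non-negative, vectorized).
#' @param compound A `compound_record` (its molecular weight is used).
#' @return Concentration in ng/mL.
#' @export
micromolar_to_mass_conc <- function(c, compound) {
  if (any(!is.finite(c)) || any(c < 0))
    stop_domain("concentration must be non-negative")
  c * compound$molecular_weight
}

#' Convert a mass concentration to a molar concentration
#'
#' Inverse of [micromolar_to_mass_conc()].
#'
#' @param c Concentration in ng/mL (non-negative, vectorized).
#' @param compound A `compound_record`.
#' @return Concentration in uM.
#' @export
mass_conc_to_micromolar <- function(c, compound) {
  if (any(!is.finite(c)) || any(c < 0))
    stop_domain("concentration must be non-negative")
  c / compound$molecular_weight
}

#' Effective inhibition constant of an inhibition specification
#'
#' Applies the sensitivity divisor (1 for measured values; 30 for the
#' EMA-style sensitivity analysis, e.g. 5 uM / 30 = 0.167 uM for ibrutinib
#' against P-gp) and then maps IC50 to Ki according to the stated
#' convention.  Default convention: Ki = IC50 (probe concentrations at or
#' below Km in the assays).
#'
#' @param spec An inhibition specification (list with `ic50`, optional
#'   `ki_convention` and `sensitivity_divisor`).
#' @param sensitivity_divisor Optional override of the divisor stored in the
#'   spec.
#' @return Effective Ki in uM.
#' @export
effective_ki <- function(spec, sensitivity_divisor = NULL) {
  validate_inhibition_spec(spec)
  div <- sensitivity_divisor %||% (spec$sensitivity_divisor %||% 1)
  check_scalar(div, "sensitivity_divisor", 1)
  ki <- spec$ic50 / div
  if ((spec$ki_convention %||% "ki_equals_ic50") == "ki_equals_ic50_over_2")
    ki <- ki / 2
  ki
}

#' Intrinsic transporter clearance Jmax/Km
#'
#' Derived accessor: the linear-regime transport clearance of a saturable
#' transporter, Jmax/Km, in uL/min/million cells (e.g. vincristine P-gp
#' 77 / 17.1 = 4.50).
#'
#' @param record A `compound_record`.
#' @param organ One of `"liver"`, `"kidney"`, `"muscle"`.
#' @param transporter Transporter name (default `"P-gp"`).
#' @return Clearance in uL/min/million cells (RAF/REF not applied).
#' @export
transporter_clint <- function(record, organ, transporter = "P-gp") {
  for (tk in record$transporter_kinetics %||% list()) {
    if (tk$transporter == transporter && tk$organ == organ)
      return(tk$j_max / tk$k_m)
  }
  stop_domain("no %s kinetics for organ '%s' in compound '%s'",
              transporter, organ, record$name)
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s (MW %.2f g/mol, %s)\n", x$name,
              x$molecular_weight, x$route))
  cat(sprintf("  fu_plasma %.3g, B/P %.3g", x$fu_plasma, x$blood_to_plasma))
  if (!is.null(x$vss_target)) cat(sprintf(", Vss target %.3g L/kg", x$vss_target))
  cat("\n")
  if (length(x$enzyme_kinetics %||% list()))
    cat(sprintf("  enzyme kinetics: %d entr%s\n", length(x$enzyme_kinetics),
                if (length(x$enzyme_kinetics) == 1) "y" else "ies"))
  if (length(x$transporter_kinetics %||% list()))
    cat(sprintf("  transporter kinetics: %s\n",
                paste(vapply(x$transporter_kinetics,
                             function(t) paste0(t$transporter, "@", t$organ),
                             character(1)), collapse = ", ")))
  if (length(x$inhibition %||% list()))
    cat(sprintf("  inhibits: %s\n",
                paste(vapply(x$inhibition, function(i)
                  sprintf("%s (IC50 %g uM, %s)", i$target, i$ic50,
                          i$assay_system %||% "?"), character(1)),
                  collapse = "; ")))
  invisible(x)
}
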