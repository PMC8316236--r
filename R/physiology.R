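# Reference human physiology and virtual oncology population sampling.

.physiology_cache <- new.env(parent = emptyenv())

physiology_tables <- function() {
  if (is.null(.physiology_cache$organs)) {
    .physiology_cache$organs <- read.csv(
      vincpbpk_file("physiology", "reference_human.csv"),
      stringsAsFactors = FALSE)
    .physiology_cache$system <- yaml::read_yaml(
      vincpbpk_file("physiology", "reference_system.yaml"))
  }
  list(organs = .physiology_cache$organs, system = .physiology_cache$system)
}

#' Reference physiology scaled to a subject
#'
#' Organ volumes scale linearly with body weight (allometric exponent 1);
#' cardiac output, regional flows and GFR scale with `(BW/70)^0.75`.
#' Volume fractions (including blood and a lumped rest-of-body organ) sum to
#' 1 of total body volume; flow fractions of the non-lung organs sum to 1 of
#' cardiac output.
#'
#' @param body_weight Body weight in kg.
#' @param sex `"male"` or `"female"` (demographic bookkeeping; the reference
#'   organ table is sex-neutral).
#' @return An object of class `system_physiology`: list with the per-organ
#'   table (`organs`: volumes L, flows L/h, tissue composition), blood
#'   volumes, cardiac output, hematocrit, GFR and liver scalars.
#' @examples
#' phys <- reference_physiology(70, "male")
#' sum(phys$organs$volume) + phys$v_blood  # ~ 70 L
#' @export
reference_physiology <- function(body_weight, sex = c("male", "female")) {
  sex <- match.arg(sex)
  check_scalar(body_weight, "body_weight", 0, Inf, lower_open = TRUE)
  tb <- physiology_tables()
  sys <- tb$system
  org <- tb$organs
  fw <- (body_weight / sys$reference_body_weight_kg)
  ff <- fw^0.75
  org$volume <- org$v_frac * body_weight        # L, density ~1 g/mL
  co <- sys$cardiac_output_l_h * ff
  org$flow <- org$q_frac * co
  org$flow[org$organ == "lung"] <- co
  structure(list(
    organs = org,
    cardiac_output = co,
    hematocrit = sys$hematocrit,
    v_blood = sys$blood_v_frac * body_weight,
    v_art = sys$blood_v_frac * body_weight * sys$arterial_frac,
    v_ven = sys$blood_v_frac * body_weight * (1 - sys$arterial_frac),
    gfr = sys$gfr_l_h * ff,
    mppgl = sys$mppgl_mg_per_g,
    hpgl = sys$hpgl_million_per_g,
    ph = list(plasma = sys$ph_plasma, ew = sys$ph_ew, iw = sys$ph_iw),
    plasma_f_nl = sys$plasma_f_nl,
    plasma_f_npl = sys$plasma_f_npl,
    body_weight = body_weight,
    sex = sex
  ), class = "system_physiology")
}

#' @export
print.system_physiology <- function(x, ...) {
  cat(sprintf("<system_physiology> %s, %.1f kg, CO %.0f L/h, %d organs\n",
              x$sex, x$body_weight, x$cardiac_output, nrow(x$organs)))
  invisible(x)
}

organ_row <- function(phys, organ) {
  i <- match(organ, phys$organs$organ)
  if (is.na(i)) stop_domain("organ '%s' not in physiology table", organ)
  phys$organs[i, ]
}

#' Specify a virtual population
#'
#' Defaults follow the oncology trial design used throughout the package:
#' 5 trials x 5 subjects, ages 20-90, 47% female, CYP3A5 non-expressor
#' (*3/*3) frequency 0.83.
#'
#' @param n_trials Number of virtual trials.
#' @param n_subjects_per_trial Subjects per trial.
#' @param age_range Two-element numeric range in years.
#' @param proportion_female Fraction of females.
#' @param cyp3a5_nonexpressor_frequency Probability a subject is *3/*3.
#' @param seed Integer seed; sampling is fully deterministic given it.
#' @param iiv_cv Log-normal coefficient of variation applied as
#'   inter-individual multipliers to CYP3A abundance, P-gp abundance and the
#'   unassigned systemic clearance (default 30%).
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_trials = 5, n_subjects_per_trial = 5,
                            age_range = c(20, 90), proportion_female = 0.47,
                            cyp3a5_nonexpressor_frequency = 0.83,
                            seed = 1L, iiv_cv = 0.30) {
  check_scalar(n_trials, "n_trials", 1)
  check_scalar(n_subjects_per_trial, "n_subjects_per_trial", 1)
  if (length(age_range) != 2 || diff(age_range) <= 0)
    stop_domain("age_range must be an increasing 2-element range")
  check_scalar(proportion_female, "proportion_female", 0, 1)
  check_scalar(cyp3a5_nonexpressor_frequency,
               "cyp3a5_nonexpressor_frequency", 0, 1)
  check_scalar(iiv_cv, "iiv_cv", 0)
  structure(list(n_trials = as.integer(n_trials),
                 n_subjects_per_trial = as.integer(n_subjects_per_trial),
                 age_range = age_range,
                 proportion_female = proportion_female,
                 cyp3a5_nonexpressor_frequency = cyp3a5_nonexpressor_frequency,
                 seed = as.integer(seed), iiv_cv = iiv_cv),
            class = "population_spec")
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Sample a virtual oncology population
#'
#' Draws `n_trials * n_subjects_per_trial` subjects: age uniform over the
#' range, sex Bernoulli, body weight from a sex-conditional log-normal
#' (medians 80 kg male / 66 kg female, 18% CV), CYP3A5 genotype i.i.d. with
#' the stated non-expressor frequency, and log-normal inter-individual
#' multipliers (mean 1) on CYP3A abundance, P-gp abundance and the
#' unassigned systemic clearance.
#'
#' @param spec A [population_spec()].
#' @param genotype_override `"none"`, `"all_poor"` or `"all_extensive"` to
#'   force the CYP3A5 class of every subject (worst-case / stratified runs).
#' @return List of `subject` objects.
#' @export
sample_population <- function(spec, genotype_override = c("none", "all_poor",
                                                          "all_extensive")) {
  stopifnot(inherits(spec, "population_spec"))
  genotype_override <- match.arg(genotype_override)
  n <- spec$n_trials * spec$n_subjects_per_trial
  set.seed(spec$seed)
  sdl <- cv_to_sdlog(spec$iiv_cv)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    age <- runif(1, spec$age_range[1], spec$age_range[2])
    sex <- if (runif(1) < spec$proportion_female) "female" else "male"
    bw_median <- if (sex == "female") 66 else 80
    bw <- rlnorm(1, meanlog = log(bw_median), sdlog = cv_to_sdlog(0.18))
    geno <- switch(genotype_override,
      none = if (runif(1) < spec$cyp3a5_nonexpressor_frequency)
               "non_expressor_star3_star3" else "expressor",
      all_poor = "non_expressor_star3_star3",
      all_extensive = "expressor")
    mult <- if (spec$iiv_cv > 0)
      rlnorm(3, meanlog = -sdl^2 / 2, sdlog = sdl) else rep(1, 3)
    subjects[[i]] <- structure(list(
      id = i,
      trial = (i - 1L) %/% spec$n_subjects_per_trial + 1L,
      age = age, sex = sex, body_weight = bw,
      cyp3a5_genotype = geno,
      multipliers = list(cyp3a = mult[1], pgp = mult[2], cl_add = mult[3]),
      physiology = reference_physiology(bw, sex)
    ), class = "subject")
  }
  subjects
}

#' A single reference subject
#'
#' Convenience constructor for deterministic runs: 70-kg subject with unit
#' variability multipliers and a chosen CYP3A5 genotype.
#'
#' @param genotype `"non_expressor_star3_star3"` (poor metabolizer, the
#'   worst-case default) or `"expressor"`.
#' @param body_weight Body weight in kg.
#' @param sex Sex.
#' @return A `subject` object.
#' @export
reference_subject <- function(genotype = c("non_expressor_star3_star3",
                                           "expressor"),
                              body_weight = 70, sex = "male") {
  genotype <- match.arg(genotype)
  structure(list(
    id = 0L, trial = 0L, age = 55, sex = sex, body_weight = body_weight,
    cyp3a5_genotype = genotype,
    multipliers = list(cyp3a = 1, pgp = 1, cl_add = 1),
    physiology = reference_physiology(body_weight, sex)
  ), class = "subject")
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf("<subject %s> %s, %.0f y, %.1f kg, CYP3A5 %s\n", x$id, x$sex,
              x$age, x$body_weight,
              if (x$cyp3a5_genotype == "expressor") "expressor" else "*3/*3"))
  invisible(x)
}
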