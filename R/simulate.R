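# ODE assembly and integration for the whole-body model.
#
# States (amounts in ug): 10 perfusion organs, lung, arterial and venous
# blood, three zones each for liver, kidney and the duplicated muscle,
# cumulative elimination fluxes, and an oral depot pair for oral victims.
# Concentrations are ug/L = ng/mL throughout; plasma concentration is
# venous blood / (B/P).

.state_names <- c(.perf_organs, "lung", "art", "ven",
                  "liv_v", "liv_e", "liv_i",
                  "kid_v", "kid_e", "kid_i",
                  "mus_v", "mus_e", "mus_i",
                  "cum_cyp3a4", "cum_cyp3a5", "cum_bile_pgp",
                  "cum_urine_pgp", "cum_urine_filt", "cum_additional",
                  "depot", "cum_unabsorbed")

assemble_engine <- function(model) {
  phys <- model$subject$physiology
  victim <- model$victim
  opts <- model$options
  org <- phys$organs
  kp <- model$partitions$kp * model$partitions$kp_scalar
  bp <- victim$blood_to_plasma
  fu_b <- victim$fu_plasma / bp

  ip <- match(.perf_organs, org$organ)
  Vp <- org$volume[ip]
  Qp <- org$flow[ip]
  kpb <- kp[.perf_organs] / bp
  imus <- match("muscle", .perf_organs)
  if (!is.null(model$pl$muscle)) Qp[imus] <- Qp[imus] * 0.5
  iportal <- match(.portal_organs, .perf_organs)
  inonportal <- setdiff(seq_along(.perf_organs), iportal)

  lung <- organ_row(phys, "lung")
  co <- phys$cardiac_output
  kpb_lung <- kp[["lung"]] / bp
  q_ha <- organ_row(phys, "liver")$flow
  q_liv_out <- q_ha + sum(Qp[iportal])

  enz <- model$enzymes
  n_enz <- length(enz)
  vmax_e <- vapply(enz, `[[`, numeric(1), "vmax")
  km_e <- vapply(enz, `[[`, numeric(1), "km_u")
  enz_names <- vapply(enz, `[[`, character(1), "enzyme")

  pl <- model$pl
  cl_add <- (victim$additional_systemic_cl %||% 0) *
    model$subject$multipliers$cl_add
  gfr_term <- if (isTRUE(opts$renal_filtration)) phys$gfr * fu_b else 0

  # inhibition factor functions (constant 1 when no perpetrator)
  if (is.null(model$inhibition_factors) && length(model$interaction_links))
    model <- apply_dynamic_inhibition(model)
  fac <- model$inhibition_factors %||% list()
  one <- function(t) 1
  f_pgp_liv <- fac[["P-gp|liver"]] %||% one
  f_pgp_kid <- fac[["P-gp|kidney"]] %||% one
  f_pgp_mus <- fac[["P-gp|muscle"]] %||% one
  f_cyp <- lapply(enz_names, function(e) fac[[paste0(e, "|liver")]] %||% one)
  has_inhibition <- length(fac) > 0

  ka <- if (victim$route == "oral") victim$absorption$ka else 0
  f_abs <- if (victim$route == "oral") victim$absorption$f_abs else 1

  list(model = model, phys = phys,
       Vp = Vp, Qp = Qp, kpb = kpb, iportal = iportal,
       inonportal = inonportal,
       v_lung = lung$volume, kpb_lung = kpb_lung, co = co,
       v_art = phys$v_art, v_ven = phys$v_ven,
       q_ha = q_ha, q_liv_out = q_liv_out,
       fu_b = fu_b, bp = bp,
       n_enz = n_enz, vmax_e = vmax_e, km_e = km_e, enz_names = enz_names,
       liv = pl$liver, kid = pl$kidney, mus = pl$muscle,
       cl_add = cl_add, gfr_term = gfr_term,
       f_pgp_liv = f_pgp_liv, f_pgp_kid = f_pgp_kid, f_pgp_mus = f_pgp_mus,
       f_cyp = f_cyp, has_inhibition = has_inhibition,
       ka = ka, f_abs = f_abs)
}

make_rhs <- function(eng) {
  force(eng)
  function(t, y, parms) {
    rate <- parms[["rate"]]
    Cp <- y[1:10] / eng$Vp
    c_lung <- y[11] / eng$v_lung
    c_art <- y[12] / eng$v_art
    c_ven <- y[13] / eng$v_ven
    cout <- Cp / eng$kpb
    dperf <- eng$Qp * (c_art - cout)
    portal_in <- sum(eng$Qp[eng$iportal] * cout[eng$iportal])

    # --- liver ---
    lv <- eng$liv
    c_lv <- y[14] / lv$v_vasc; c_le <- y[15] / lv$v_ew; c_li <- y[16] / lv$v_iw
    j_ve_l <- lv$ps_vasc * (c_lv * eng$fu_b - c_le * lv$fu_ew)
    cu_li <- c_li * lv$fu_iw_eff
    j_ei_l <- lv$ps_pd * (c_le * lv$fu_ew - cu_li)
    met <- numeric(eng$n_enz)
    if (eng$n_enz) {
      for (j in seq_len(eng$n_enz)) {
        kmj <- eng$km_e[j]
        if (eng$has_inhibition) kmj <- kmj * eng$f_cyp[[j]](t)
        met[j] <- eng$vmax_e[j] * cu_li / (kmj + cu_li)
      }
    }
    pgp_l <- if (lv$jmax > 0) {
      kml <- lv$km_pgp
      if (eng$has_inhibition) kml <- kml * eng$f_pgp_liv(t)
      lv$jmax * cu_li / (kml + cu_li)
    } else 0
    absorbed <- eng$ka * y[29] * eng$f_abs
    d_lv <- eng$q_ha * c_art + portal_in + absorbed -
      eng$q_liv_out * c_lv - j_ve_l
    d_le <- j_ve_l - j_ei_l
    d_li <- j_ei_l - sum(met) - pgp_l

    # --- kidney ---
    kd <- eng$kid
    c_kv <- y[17] / kd$v_vasc; c_ke <- y[18] / kd$v_ew; c_ki <- y[19] / kd$v_iw
    q_kid <- kd$q
    j_ve_k <- kd$ps_vasc * (c_kv * eng$fu_b - c_ke * kd$fu_ew)
    cu_ki <- c_ki * kd$fu_iw_eff
    j_ei_k <- kd$ps_pd * (c_ke * kd$fu_ew - cu_ki)
    pgp_k <- if (kd$jmax > 0) {
      kmk <- kd$km_pgp
      if (eng$has_inhibition) kmk <- kmk * eng$f_pgp_kid(t)
      kd$jmax * cu_ki / (kmk + cu_ki)
    } else 0
    filt <- eng$gfr_term * c_kv
    d_kv <- q_kid * (c_art - c_kv) - j_ve_k - filt
    d_ke <- j_ve_k - j_ei_k
    d_ki <- j_ei_k - pgp_k

    # --- duplicated permeability-limited muscle ---
    if (!is.null(eng$mus)) {
      ms <- eng$mus
      c_mv <- y[20] / ms$v_vasc; c_me <- y[21] / ms$v_ew; c_mi <- y[22] / ms$v_iw
      j_ve_m <- ms$ps_vasc * (c_mv * eng$fu_b - c_me * ms$fu_ew)
      cu_mi <- c_mi * ms$fu_iw_eff
      j_ei_m <- ms$ps_pd * (c_me * ms$fu_ew - cu_mi)
      pgp_m <- if (ms$jmax > 0) {
        kmm <- ms$km_pgp
        if (eng$has_inhibition) kmm <- kmm * eng$f_pgp_mus(t)
        ms$jmax * cu_mi / (kmm + cu_mi)
      } else 0
      d_mv <- ms$q * (c_art - c_mv) - j_ve_m
      d_me <- j_ve_m - j_ei_m + pgp_m
      d_mi <- j_ei_m - pgp_m
      mus_return <- ms$q * c_mv
    } else {
      d_mv <- d_me <- d_mi <- 0
      mus_return <- 0
    }

    add_flux <- eng$cl_add * c_ven / eng$bp
    ven_in <- sum(eng$Qp[eng$inonportal] * cout[eng$inonportal]) +
      eng$q_liv_out * c_lv + q_kid * c_kv + mus_return
    d_ven <- ven_in - eng$co * c_ven + rate - add_flux
    d_lung <- eng$co * (c_ven - c_lung / eng$kpb_lung)
    d_art <- eng$co * (c_lung / eng$kpb_lung - c_art)

    d_depot <- -eng$ka * y[29]
    d_unabs <- eng$ka * y[29] * (1 - eng$f_abs)

    met3a4 <- sum(met[eng$enz_names == "CYP3A4"])
    met3a5 <- sum(met[eng$enz_names == "CYP3A5"])

    list(c(dperf, d_lung, d_art, d_ven,
           d_lv, d_le, d_li, d_kv, d_ke, d_ki, d_mv, d_me, d_mi,
           met3a4, met3a5, pgp_l, pgp_k, filt, add_flux,
           d_depot, d_unabs))
  }
}

#' Simulate a PBPK model
#'
#' Integrates the whole-body ODE system with a stiff solver (`lsoda`,
#' default tolerances 1e-8 relative / 1e-10 absolute) on a uniform
#' reporting grid, tracking cumulative elimination fluxes alongside the
#' states.  The infusion is handled by exact segmentation at the end of
#' infusion, so mass balance holds to solver tolerance at every reported
#' time.
#'
#' @param model A [pbpk_model()].
#' @param horizon Simulation end time in h.
#' @param dt Reporting grid step (h); defaults to the model option.
#' @return An object of class `pbpk_sim`: reporting `time`, `conc` matrix
#'   (ng/mL) with plasma, blood and organ-zone concentrations plus the
#'   permeability-limited muscle tissue concentration, cumulative `fluxes`
#'   (mg), the raw state matrix, and `mass_balance_rel_error`.
#' @export
simulate_pbpk <- function(model, horizon = 96, dt = NULL) {
  stopifnot(inherits(model, "pbpk_model"))
  check_scalar(horizon, "horizon", 0, Inf, lower_open = TRUE)
  if (length(model$interaction_links) && is.null(model$inhibition_factors))
    model <- apply_dynamic_inhibition(model)
  eng <- assemble_engine(model)
  rhs <- make_rhs(eng)
  opts <- model$options
  dt <- dt %||% opts$dt_report
  dose_ug <- model$dosing$amount * 1000

  y0 <- setNames(numeric(length(.state_names)), .state_names)
  segs <- list()
  if (model$dosing$route == "iv_infusion") {
    dur <- model$dosing$infusion_duration
    rate <- dose_ug / dur
    segs <- list(list(t0 = 0, t1 = min(dur, horizon), rate = rate))
    if (horizon > dur)
      segs <- c(segs, list(list(t0 = dur, t1 = horizon, rate = 0)))
  } else {
    y0["depot"] <- dose_ug
    segs <- list(list(t0 = 0, t1 = horizon, rate = 0))
  }

  out <- NULL
  y <- y0
  for (sg in segs) {
    times <- unique(sort(c(sg$t0, seq(ceiling(sg$t0 / dt) * dt, sg$t1, by = dt),
                           sg$t1)))
    if (length(times) < 2) times <- c(sg$t0, sg$t1)
    sol <- deSolve::lsoda(y, times, rhs, parms = list(rate = sg$rate),
                          rtol = opts$rtol, atol = opts$atol, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      stop_domain("solver failure at t = %.4g h", sol[nrow(sol), 1])
    y <- sol[nrow(sol), -1]
    out <- if (is.null(out)) sol else rbind(out[-nrow(out), , drop = FALSE], sol)
  }
  time <- out[, 1]
  states <- out[, -1, drop = FALSE]
  colnames(states) <- .state_names

  delivered <- if (model$dosing$route == "iv_infusion")
    dose_ug * pmin(time / model$dosing$infusion_duration, 1) else dose_ug
  total <- rowSums(states)
  mb <- max(abs(total - delivered)) / dose_ug

  phys <- model$subject$physiology
  mus <- model$pl$muscle
  conc <- cbind(
    plasma = states[, "ven"] / eng$v_ven / eng$bp,
    venous_blood = states[, "ven"] / eng$v_ven,
    arterial_blood = states[, "art"] / eng$v_art,
    liver_vasc = states[, "liv_v"] / eng$liv$v_vasc,
    liver_ew = states[, "liv_e"] / eng$liv$v_ew,
    liver_iw = states[, "liv_i"] / eng$liv$v_iw,
    kidney_iw = states[, "kid_i"] / eng$kid$v_iw,
    muscle_tissue = if (!is.null(mus))
      (states[, "mus_v"] + states[, "mus_e"] + states[, "mus_i"]) / mus$v_total
      else NA_real_,
    muscle_iw = if (!is.null(mus)) states[, "mus_i"] / mus$v_iw else NA_real_
  )
  fluxes <- data.frame(
    time = time,
    cyp3a4 = states[, "cum_cyp3a4"] / 1000,
    cyp3a5 = states[, "cum_cyp3a5"] / 1000,
    bile_pgp = states[, "cum_bile_pgp"] / 1000,
    urine_pgp = states[, "cum_urine_pgp"] / 1000,
    urine_filtration = states[, "cum_urine_filt"] / 1000,
    additional = states[, "cum_additional"] / 1000
  )
  fluxes$total_eliminated <- rowSums(fluxes[, -1])

  structure(list(time = time, conc = conc, fluxes = fluxes,
                 states = states, dose_mg = model$dosing$amount,
                 model = model,
                 mass_balance_rel_error = mb),
            class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s, %.3g mg, t 0-%.4g h (%d points)\n",
              x$model$victim$name, x$dose_mg, max(x$time), length(x$time)))
  cat(sprintf("  Cmax plasma %.4g ng/mL; eliminated %.1f%% of dose; mass balance %.2g\n",
              max(x$conc[, "plasma"]),
              100 * x$fluxes$total_eliminated[nrow(x$fluxes)] / x$dose_mg,
              x$mass_balance_rel_error))
  invisible(x)
}

#' Simulate method for PBPK models
#'
#' Interface to [simulate_pbpk()] following the classic `simulate()`
#' generic: returns one `pbpk_sim` (or a list for `nsim > 1`, which for
#' this deterministic engine are identical replicates).
#'
#' @param object A `pbpk_model`.
#' @param nsim Number of simulations.
#' @param seed Unused (the engine is deterministic; population variability
#'   lives in the subject sampling).
#' @param horizon,dt Passed to [simulate_pbpk()].
#' @param ... Unused.
#' @return A `pbpk_sim` or list thereof.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL,
                                horizon = 96, dt = NULL, ...) {
  if (nsim == 1) return(simulate_pbpk(object, horizon = horizon, dt = dt))
  lapply(seq_len(nsim), function(i) simulate_pbpk(object, horizon = horizon,
                                                  dt = dt))
}

#' Plot a simulated profile
#'
#' Semi-log plasma concentration-time profile, with the
#' permeability-limited muscle tissue concentration overlaid when present.
#'
#' @param x A `pbpk_sim`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.pbpk_sim <- function(x, ...) {
  keep <- x$conc[, "plasma"] > 0
  plot(x$time[keep], x$conc[keep, "plasma"], type = "l", log = "y",
       xlab = "time (h)", ylab = "concentration (ng/mL)", ...)
  if (!all(is.na(x$conc[, "muscle_tissue"]))) {
    km <- x$conc[, "muscle_tissue"] > 0
    graphics::lines(x$time[km], x$conc[km, "muscle_tissue"], lty = 2)
    graphics::legend("topright", c("plasma", "muscle tissue"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

trapz <- function(x, y) sum(diff(x) * (head_(y) + tail_(y)) / 2)
head_ <- function(y) y[-length(y)]
tail_ <- function(y) y[-1]

#' Renal clearance derived from the kidney transport model
#'
#' Runs a linear-regime simulation of the model to near-complete
#' elimination and returns total urinary excretion flux divided by plasma
#' AUC, i.e. the model-predicted renal clearance (P-gp tubular secretion
#' plus filtration when enabled).
#'
#' @param model A `pbpk_model`.
#' @param horizon Simulation horizon (h); should cover essentially complete
#'   elimination.
#' @return Renal clearance in L/h, with attribute `sim` carrying the run.
#' @export
derive_renal_clearance <- function(model, horizon = 600) {
  sim <- simulate_pbpk(model, horizon = horizon, dt = 0.1)
  cu_max <- max(sim$conc[, "kidney_iw"]) * model$pl$kidney$fu_iw_eff
  if (model$pl$kidney$jmax > 0 && cu_max > 0.1 * model$pl$kidney$km_pgp)
    warning("kidney intracellular concentrations approach Km; renal ",
            "clearance is concentration-dependent", call. = FALSE)
  urine <- sim$fluxes$urine_pgp[nrow(sim$fluxes)] +
    sim$fluxes$urine_filtration[nrow(sim$fluxes)]
  auc <- trapz(sim$time, sim$conc[, "plasma"]) / 1000   # mg h / L
  cl <- urine / auc
  attr(cl, "sim") <- sim
  cl
}
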