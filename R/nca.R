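# Non-compartmental analysis: linear-up/log-down AUC, terminal slope by
# best-adjusted-r2 log-linear regression, and the derived CL/V parameters.

#' Linear-up/log-down trapezoidal AUC over an interval
#'
#' Uses the linear trapezoid where concentration rises or is flat and the
#' logarithmic trapezoid where it falls (both endpoints positive);
#' interpolates linearly at interior window edges.
#'
#' @param time Time vector (h), strictly increasing.
#' @param conc Concentrations (ng/mL), same length; NA (below
#'   quantification) points are dropped.
#' @param from,to Window edges in h (default: whole profile).
#' @return AUC in ng h/mL.
#' @export
auc_trapezoid <- function(time, conc, from = min(time), to = max(time)) {
  keep <- !is.na(conc)
  time <- time[keep]; conc <- conc[keep]
  if (length(time) < 2) stop_domain("need at least two quantifiable points")
  if (is.unsorted(time, strictly = TRUE)) stop_domain("time must be increasing")
  interp <- function(tt) {
    if (tt <= time[1]) return(conc[1])
    if (tt >= time[length(time)]) return(conc[length(conc)])
    stats::approx(time, conc, xout = tt)$y
  }
  sel <- time > from & time < to
  tt <- c(from, time[sel], to)
  cc <- c(interp(from), conc[sel], interp(to))
  auc <- 0
  for (i in seq_len(length(tt) - 1)) {
    dtt <- tt[i + 1] - tt[i]
    c1 <- cc[i]; c2 <- cc[i + 1]
    auc <- auc + if (c2 < c1 && c2 > 0 && c1 > 0)
      dtt * (c1 - c2) / log(c1 / c2) else dtt * (c1 + c2) / 2
  }
  auc
}

terminal_slope <- function(time, conc, min_points = 3, max_points = 12) {
  pos <- which(!is.na(conc) & conc > 0)
  if (!length(pos)) return(NULL)
  imax <- pos[which.max(conc[pos])]
  cand <- pos[pos > imax]          # strictly after Cmax
  n <- length(cand)
  if (n < min_points) return(NULL)
  best <- NULL
  for (k in min_points:min(n, max_points)) {
    idx <- cand[(n - k + 1):n]
    tt <- time[idx]; lc <- log(conc[idx])
    fit <- lm(lc ~ tt)
    sl <- unname(coef(fit)[2])
    if (!is.finite(sl) || sl >= 0) next
    r2 <- suppressWarnings(summary(fit)$r.squared)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (adj > best$adj - 1e-4 && k > best$k)) {
      if (is.null(best) || adj > best$adj - 1e-4)
        best <- list(lambda_z = -sl, k = k, adj_r2 = adj, idx = idx)
    }
  }
  best
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Computes Cmax/tmax, linear-up/log-down AUC to the last quantifiable
#' point, the terminal slope by log-linear regression over the
#' best-adjusted-r2 tail (>= 3 points, excluding Cmax), AUC extrapolated to
#' infinity, clearance, terminal volume (Vz = CL/lambda_z) and half-life.
#'
#' @param time Sampling times (h).
#' @param conc Concentrations (ng/mL); NA marks below-quantification
#'   samples.
#' @param dose Dose in mg (needed for CL).
#' @param body_weight Body weight in kg (for Vd in L/kg); optional.
#' @param lloq Optional lower limit of quantification in ng/mL;
#'   concentrations below it are censored before analysis.
#' @return An object of class `nca` with fields `auc_0_t`, `auc_0_inf`,
#'   `auc_0_24` (ng h/mL), `cmax` (ng/mL), `tmax` (h), `half_life` (h),
#'   `lambda_z` (1/h), `cl` (mL/min), `vd` (L/kg or L), `
#'   extrapolated_fraction` and regression diagnostics.
#' @export
nca <- function(time, conc, dose = NULL, body_weight = NULL, lloq = NULL) {
  if (length(time) != length(conc)) stop_domain("time/conc length mismatch")
  if (!is.null(lloq)) conc[!is.na(conc) & conc < lloq] <- NA
  if (all(is.na(conc)) || all(conc[!is.na(conc)] <= 0))
    stop_domain("profile has no positive quantifiable concentrations")
  if (any(conc[!is.na(conc)] < 0)) stop_domain("negative concentrations")
  ok <- which(!is.na(conc) & conc > 0)
  cmax <- max(conc[ok]); tmax <- time[ok[which.max(conc[ok])]]
  last <- ok[length(ok)]
  auc_t <- auc_trapezoid(time, conc, from = time[1], to = time[last])
  auc_24 <- if (time[last] >= 24)
    auc_trapezoid(time, conc, from = time[1], to = 24) else NA_real_

  ts <- terminal_slope(time, conc)
  if (is.null(ts)) {
    res <- list(auc_0_t = auc_t, auc_0_inf = NA_real_, auc_0_24 = auc_24,
                cmax = cmax, tmax = tmax, half_life = NA_real_,
                lambda_z = NA_real_, cl = NA_real_, vd = NA_real_,
                extrapolated_fraction = NA_real_, adj_r2 = NA_real_,
                n_tail = 0L, terminal_phase = FALSE)
    return(structure(res, class = "nca"))
  }
  clast <- conc[last]
  auc_inf <- auc_t + clast / ts$lambda_z
  cl_ml_min <- if (!is.null(dose)) dose * 1e6 / auc_inf / 60 else NA_real_
  vz <- if (!is.null(dose)) {
    v_l <- (dose * 1e6 / auc_inf) / ts$lambda_z / 1000   # L
    if (!is.null(body_weight)) v_l / body_weight else v_l
  } else NA_real_
  structure(list(
    auc_0_t = auc_t, auc_0_inf = auc_inf, auc_0_24 = auc_24,
    cmax = cmax, tmax = tmax,
    half_life = log(2) / ts$lambda_z, lambda_z = ts$lambda_z,
    cl = cl_ml_min, vd = vz,
    extrapolated_fraction = (auc_inf - auc_t) / auc_inf,
    adj_r2 = ts$adj_r2, n_tail = ts$k, terminal_phase = TRUE
  ), class = "nca")
}

#' @export
print.nca <- function(x, ...) {
  cat("<nca>\n")
  cat(sprintf("  Cmax %.4g ng/mL at %.3g h; AUC0-t %.4g, AUC0-inf %.4g ng.h/mL\n",
              x$cmax, x$tmax, x$auc_0_t, x$auc_0_inf))
  if (isTRUE(x$terminal_phase))
    cat(sprintf("  t1/2 %.4g h (lambda_z %.4g /h, %d points, adj r2 %.4f); CL %.4g mL/min; Vz %.4g\n",
                x$half_life, x$lambda_z, x$n_tail, x$adj_r2, x$cl, x$vd))
  else cat("  no terminal phase identifiable\n")
  invisible(x)
}

#' NCA of a simulated profile on a clinical sampling schedule
#'
#' Samples the simulated plasma profile at the given schedule, censors
#' below the LLOQ, and runs [nca()] - i.e. analyses the simulation the way
#' an observed clinical profile would be analysed.
#'
#' @param sim A `pbpk_sim`.
#' @param times Sampling schedule (h); defaults to a rich oncology PK
#'   schedule over 0-96 h.
#' @param lloq Lower limit of quantification (ng/mL); default 0.05, a
#'   typical LC-MS/MS sensitivity for vincristine in plasma.
#' @param compartment Column of `sim$conc` to analyse (default plasma).
#' @return An `nca` object.
#' @export
nca_from_sim <- function(sim, times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 36,
                                        48, 72, 96),
                         lloq = 0.05, compartment = "plasma") {
  stopifnot(inherits(sim, "pbpk_sim"))
  times <- times[times <= max(sim$time)]
  cc <- stats::approx(sim$time, sim$conc[, compartment], xout = times)$y
  nca(times, cc, dose = sim$dose_mg,
      body_weight = sim$model$subject$body_weight, lloq = lloq)
}
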