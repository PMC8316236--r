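# In vitro transport computations: efflux ratios, ATP-dependent vesicular
# transport, four-parameter IC50 curves (linear- and log-concentration
# parameterizations) and Michaelis-Menten transport kinetics.

#' Efflux ratio from bidirectional permeabilities
#'
#' Ratio of basolateral-to-apical over apical-to-basolateral apparent
#' permeability across a cell monolayer; values > 1 indicate net efflux.
#'
#' @param papp_ab Apical-to-basolateral permeability (1e-6 cm/s), > 0.
#' @param papp_ba Basolateral-to-apical permeability (1e-6 cm/s), > 0.
#' @return The unitless efflux ratio `papp_ba / papp_ab`.
#' @export
efflux_ratio <- function(papp_ab, papp_ba) {
  if (any(papp_ab <= 0) || any(papp_ba <= 0))
    stop_domain("permeabilities must be positive")
  papp_ba / papp_ab
}

#' ATP-dependent vesicular transport
#'
#' Transporter-mediated uptake into inside-out membrane vesicles is the
#' accumulation in ATP-containing assays minus the background accumulation
#' in AMP-containing assays.  Negative differences are clipped to zero and
#' flagged (physical non-negativity).
#'
#' @param atp_signal Accumulation with ATP (pmol/mg protein/min).
#' @param amp_signal Background accumulation with AMP, same length.
#' @return Numeric vector of net transport with attribute `clipped`
#'   (logical vector marking clipped entries).
#' @export
atp_dependent_transport <- function(atp_signal, amp_signal) {
  if (length(atp_signal) != length(amp_signal))
    stop_domain("ATP and AMP signal vectors must have the same length")
  net <- atp_signal - amp_signal
  clipped <- net < 0
  if (any(clipped)) {
    net[clipped] <- 0
    warning("negative ATP-dependent transport clipped to 0", call. = FALSE)
  }
  attr(net, "clipped") <- clipped
  net
}


# Levenberg-Marquardt least-squares driver shared by the curve fitters.
lm_curve_fit <- function(pred_fn, obs, start, w, lower = NULL) {
  sw <- sqrt(w)
  resid_fn <- function(p) sw * (obs - pred_fn(p))
  out <- try(minpack.lm::nls.lm(
    par = start, fn = resid_fn, lower = lower,
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(out, "try-error"))
    return(list(ok = FALSE, message = as.character(out)))
  par <- unlist(out$par)
  ok <- out$info %in% 1:4 && all(is.finite(par))
  list(ok = ok, par = par,
       message = if (!ok) paste("nls.lm info", out$info) else NULL)
}

new_ic50_fit <- function(pars, converged, model, data,
                         message = NULL) {
  structure(list(
    ic50 = unname(pars["ic50"]), hill = unname(pars["hill"]),
    top = unname(pars["top"]), bottom = unname(pars["bottom"]),
    km = unname(pars["km"]), vmax = unname(pars["vmax"]),
    convergence_flag = if (converged) "converged" else "failed",
    model = model, data = data, message = message
  ), class = "ic50_fit")
}

ic50_start <- function(conc, resp) {
  top0 <- max(resp); bot0 <- min(resp)
  mid <- (top0 + bot0) / 2
  # concentration bracketing the 50% response
  below <- which(resp <= mid)
  ic50_0 <- if (length(below)) conc[below[1]] else stats::median(conc)
  if (!is.finite(ic50_0) || ic50_0 <= 0) ic50_0 <- stats::median(conc)
  c(top = top0, bottom = bot0, ic50 = ic50_0, hill = 1)
}

#' Fit an inhibition curve on a linear concentration axis
#'
#' Four-parameter logistic in the concentration domain,
#' `Y = bottom + (top - bottom) / (1 + (conc/IC50)^hill)`,
#' fit by unweighted nonlinear least squares.  Top and bottom are not
#' constrained to 100 and 0.  Used for cell-based assays where the response
#' is an efflux ratio or uptake rate as percent of control.
#'
#' @param concentrations Inhibitor concentrations in uM (>= 4 distinct).
#' @param responses Responses (percent of control), same length.
#' @param weights Optional `"relative"` for 1/Y^2 weighting (default
#'   unweighted).
#' @return An `ic50_fit`; non-convergence or unidentifiable (flat) data
#'   yield `convergence_flag = "failed"` instead of an error.
#' @export
fit_ic50_cell <- function(concentrations, responses, weights = c("none", "relative")) {
  weights <- match.arg(weights)
  if (length(unique(concentrations)) < 4)
    stop_domain("need at least 4 distinct concentrations")
  if (any(concentrations <= 0)) stop_domain("concentrations must be positive")
  df <- data.frame(conc = concentrations, resp = responses)
  start <- ic50_start(df$conc, df$resp)
  if (diff(range(df$resp)) < 1e-10 * max(1, abs(mean(df$resp))))
    return(new_ic50_fit(c(start, ic50 = NA_real_)[c("top", "bottom", "ic50", "hill")],
                        FALSE, "cell_linear", df, "flat response; IC50 unidentifiable"))
  w <- if (weights == "relative") 1 / pmax(df$resp, 1e-12)^2 else rep(1, nrow(df))
  fit <- lm_curve_fit(function(p) p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
                        (1 + (df$conc / p[["ic50"]])^p[["hill"]]),
                      df$resp, as.list(start), w,
                      lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-12,
                                hill = 1e-6))
  if (!fit$ok)
    return(new_ic50_fit(start, FALSE, "cell_linear", df, fit$message))
  new_ic50_fit(fit$par, TRUE, "cell_linear", df)
}

#' Fit an inhibition curve on a log10 concentration axis
#'
#' Four-parameter logistic in the log domain,
#' `Y = bottom + (top - bottom) / (1 + 10^((logIC50 - X) * hill))`,
#' with `X = log10(concentration)`; the standard parameterization for
#' vesicular transport inhibition (relative activity vs log concentration).
#' Identical curves expressed in either parameterization give the same IC50
#' as [fit_ic50_cell()] when `hill` there equals `-hill` slope sign here
#' (both report positive IC50 and Hill factor).
#'
#' @param log_concentrations log10 of inhibitor concentrations (uM).
#' @param responses Relative activity, same length.
#' @inheritParams fit_ic50_cell
#' @return An `ic50_fit`.
#' @export
fit_ic50_vesicle <- function(log_concentrations, responses,
                             weights = c("none", "relative")) {
  weights <- match.arg(weights)
  if (length(unique(log_concentrations)) < 4)
    stop_domain("need at least 4 distinct concentrations")
  df <- data.frame(x = log_concentrations, resp = responses)
  conc <- 10^df$x
  start <- ic50_start(conc, df$resp)
  if (diff(range(df$resp)) < 1e-10 * max(1, abs(mean(df$resp))))
    return(new_ic50_fit(c(top = start[["top"]], bottom = start[["bottom"]],
                          ic50 = NA_real_, hill = NA_real_),
                        FALSE, "vesicle_log", df, "flat response; IC50 unidentifiable"))
  # in the log parameterization a response that falls with concentration
  # carries a negative Hill slope
  hill0 <- if (isTRUE(stats::cor(df$x, df$resp) < 0)) -1 else 1
  start_l <- list(top = start[["top"]], bottom = start[["bottom"]],
                  logic50 = log10(start[["ic50"]]), hill = hill0)
  w <- if (weights == "relative") 1 / pmax(df$resp, 1e-12)^2 else rep(1, nrow(df))
  fit <- lm_curve_fit(function(p) p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
                        (1 + 10^((p[["logic50"]] - df$x) * p[["hill"]])),
                      df$resp, start_l, w)
  if (!fit$ok)
    return(new_ic50_fit(c(top = NA, bottom = NA, ic50 = NA, hill = NA),
                        FALSE, "vesicle_log", df, fit$message))
  cf <- fit$par
  hill <- unname(cf["hill"])
  pars <- c(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
            ic50 = 10^unname(cf["logic50"]), hill = abs(hill))
  converged <- is.finite(pars["ic50"]) && abs(hill) > 1e-6
  new_ic50_fit(pars, converged, "vesicle_log", df,
               if (!converged) "Hill slope ~ 0; IC50 unidentifiable")
}

#' Fit Michaelis-Menten transport kinetics
#'
#' `v = Vmax * S / (Km + S)` by nonlinear least squares, for
#' substrate-dependent transporter rates (e.g. vincristine vesicular
#' transport over 0.13-200 uM).
#'
#' @param substrate_conc Substrate concentrations in uM (>= 5, spanning
#'   above and below Km for identifiability).
#' @param rates Transport rates (pmol/mg protein/min).
#' @return An `ic50_fit` carrying `km` and `vmax`; an all-saturated design
#'   (no concentration below twice the fitted Km) is flagged
#'   `"failed"` as unidentifiable.
#' @export
fit_mm_transport <- function(substrate_conc, rates) {
  if (length(unique(substrate_conc)) < 5)
    stop_domain("need at least 5 distinct substrate concentrations")
  if (any(substrate_conc <= 0)) stop_domain("concentrations must be positive")
  df <- data.frame(s = substrate_conc, v = rates)
  vmax0 <- max(df$v)
  km0 <- {
    half <- which(df$v >= vmax0 / 2)
    if (length(half)) max(min(df$s[half]), min(df$s)) else stats::median(df$s)
  }
  fit <- lm_curve_fit(function(p) p[["vmax"]] * df$s / (p[["km"]] + df$s),
                      df$v, list(vmax = vmax0, km = km0), rep(1, nrow(df)),
                      lower = c(vmax = 0, km = 1e-12))
  if (!fit$ok)
    return(new_ic50_fit(c(km = NA, vmax = NA, ic50 = NA, hill = NA),
                        FALSE, "michaelis_menten", df, fit$message))
  cf <- as.list(fit$par)
  identifiable <- min(df$s) < 2 * cf[["km"]] && cf[["km"]] < 50 * max(df$s)
  new_ic50_fit(c(km = cf[["km"]], vmax = cf[["vmax"]],
                 ic50 = NA_real_, hill = NA_real_),
               identifiable, "michaelis_menten", df,
               if (!identifiable) "design does not bracket Km; unidentifiable")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> model %s [%s]\n", x$model, x$convergence_flag))
  if (x$model == "michaelis_menten")
    cat(sprintf("  Km %.4g uM, Vmax %.4g\n", x$km, x$vmax))
  else
    cat(sprintf("  IC50 %.4g uM, Hill %.3g, top %.4g, bottom %.4g\n",
                x$ic50, x$hill, x$top, x$bottom))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

#' @export
coef.ic50_fit <- function(object, ...) {
  if (object$model == "michaelis_menten")
    c(km = object$km, vmax = object$vmax)
  else
    c(ic50 = object$ic50, hill = object$hill,
      top = object$top, bottom = object$bottom)
}

#' Predicted response of a fitted in vitro curve
#'
#' @param object An `ic50_fit`.
#' @param newdata Optional vector of concentrations (uM; linear scale, also
#'   for the log-parameterized model) or substrate concentrations.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.ic50_fit <- function(object, newdata = NULL, ...) {
  conc <- newdata %||% switch(object$model,
    vesicle_log = 10^object$data$x,
    michaelis_menten = object$data$s,
    object$data$conc)
  switch(object$model,
    michaelis_menten = object$vmax * conc / (object$km + conc),
    object$bottom + (object$top - object$bottom) /
      (1 + (conc / object$ic50)^object$hill))
}

#' Plot a fitted in vitro curve with its data
#'
#' @param x An `ic50_fit`.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.ic50_fit <- function(x, ...) {
  conc <- switch(x$model, vesicle_log = 10^x$data$x,
                 michaelis_menten = x$data$s, x$data$conc)
  resp <- if (x$model == "michaelis_menten") x$data$v else x$data$resp
  grid <- exp(seq(log(min(conc)), log(max(conc)), length.out = 100))
  plot(conc, resp, log = "x",
       xlab = "concentration (uM)", ylab = "response", ...)
  graphics::lines(grid, predict(x, grid))
  invisible(x)
}
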