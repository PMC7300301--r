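# Target-mediated drug disposition: printed three-state ODE block
# (free drug D, free target R, drug-target complex C) with reversible
# binding, target turnover towards R0, and complex degradation.

#' TMDD rate equations
#'
#' Right-hand sides of the target-binding system, per extracellular
#' compartment:
#' \deqn{dD/dt = -kon D R + koff C}
#' \deqn{dC/dt = kon D R - koff C - kdeg C}
#' \deqn{dR/dt = ksyn (R0 - R) - kon D R + koff C}
#'
#' @param state Named list or vector with elements `D`, `R`, `C`
#'   (concentrations, uM; non-negative).
#' @param p A [tmdd_parameters()] object.
#' @return Named numeric vector `c(dD, dC, dR)` in uM/day.
#' @examples
#' p <- tmdd_parameters(0.058, 3.1e-5, 0.401, 0.0482, 0.0113)
#' tmdd_rates(c(D = 0, R = 0.0113, C = 0), p)  # drug-free steady state
#' @export
tmdd_rates <- function(state, p) {
  stopifnot(inherits(p, "tmdd_parameters"))
  s <- as.list(state)
  stopifnot(s$D >= 0, s$R >= 0, s$C >= 0)
  bind <- p$kon * s$D * s$R
  unb <- p$koff_day * s$C
  c(dD = -bind + unb,
    dC = bind - unb - p$kdeg_complex * s$C,
    dR = p$ksyn * (p$r0 - s$R) - bind + unb)
}

#' Attach target-mediated disposition to a PBPK model
#'
#' Adds free-target and complex states at uniform initial concentration `R0`
#' to every extracellular subcompartment (organ plasma and interstitial
#' spaces plus the venous and arterial pools), coupling [tmdd_rates()] into
#' the drug's equations.  The target concentration is age-independent and
#' spatially uniform.
#'
#' @param model A `pbpk_model` without TMDD.
#' @param p A [tmdd_parameters()] object, or `NULL` (by default taken from
#'   the model's drug definition).  `NULL` returns the model unchanged.
#' @return The extended `pbpk_model`.
#' @export
attach_tmdd <- function(model, p = model$drug$tmdd) {
  stopifnot(inherits(model, "pbpk_model"))
  if (!is.null(model$tmdd)) stop("model already has TMDD attached")
  if (is.null(p)) return(model)
  stopifnot(inherits(p, "tmdd_parameters"))
  model$tmdd <- p
  model
}

#' Fit TMDD parameters and FcRn affinity to observed profiles
#'
#' Weighted least squares on log concentrations across all dose groups
#' simultaneously (proportional-error weighting), estimating the FcRn
#' dissociation constant together with the target reference concentration
#' `r0` and the complex degradation rate `kdeg_complex`; the remaining TMDD
#' parameters (target affinity, `koff`, `ksyn`) are fixed at their inputs.
#'
#' @param observed A data.frame with columns `time_days`, `conc_ug_ml` and
#'   `dose_mg_kg` (one profile per dose group; concentrations must be
#'   positive), e.g. from [generate_observed()], or a list of `pk_profile`s.
#' @param model_template A `pbpk_model` (adult physiology, no TMDD attached)
#'   whose drug carries the fixed TMDD constants.
#' @param start Named starting values `c(kd_fcrn, r0, kdeg_complex)`.
#' @param days,dt Simulation support; predictions are interpolated to the
#'   observed times from a grid with step `dt` out to `days` (defaults cover
#'   the observation window).
#' @param rtol,atol Solver tolerances used during fitting.
#' @param control `minpack.lm::nls.lm.control()` list.
#' @return An object of class `tmdd_fit` with elements `par` (point
#'   estimates), `fitted_drug` (a `drug_properties` with the fitted values),
#'   `residual_sd` (log scale), `convergence` and the `nls.lm` report.
#' @export
fit_tmdd_and_fcrn <- function(observed, model_template,
                              start = c(kd_fcrn = 0.4, r0 = 0.004,
                                        kdeg_complex = 0.15),
                              days = NULL, dt = 0.5,
                              rtol = 1e-6, atol = 1e-8,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 30, ftol = 1e-8, epsfcn = 1e-4)) {
  stopifnot(inherits(model_template, "pbpk_model"), is.null(model_template$tmdd))
  if (is.list(observed) && !is.data.frame(observed))
    observed <- do.call(rbind, lapply(observed, function(p)
      cbind(as.data.frame(p), dose_mg_kg = attr(p, "meta")$dose_mg_kg)))
  stopifnot(all(c("time_days", "conc_ug_ml", "dose_mg_kg") %in% names(observed)))
  observed <- observed[is.finite(observed$conc_ug_ml) & observed$conc_ug_ml > 0, ]
  doses <- sort(unique(observed$dose_mg_kg))
  if (length(doses) < 2)
    warning("fewer than 2 dose groups: r0 is likely practically unidentifiable")
  if (is.null(days)) days <- max(observed$time_days)
  grid <- sort(unique(c(seq(0, days, by = dt), observed$time_days)))
  tm0 <- model_template$drug$tmdd
  if (is.null(tm0)) tm0 <- tmdd_parameters(0.058, 3.1e-5, 0.401, 0.0482, 1)
  pred_log <- function(par) {
    kd <- exp(par[1]); r0 <- exp(par[2]); kdeg <- exp(par[3])
    m <- .pbpk_set_kd(model_template, kd)
    m$drug$tmdd <- tmdd_parameters(tm0$kd_target, tm0$koff, tm0$ksyn, kdeg, r0)
    m <- attach_tmdd(m)
    unlist(lapply(doses, function(d) {
      prof <- simulate_pbpk(m, dose_regimen(d), grid, rtol = rtol, atol = atol)
      obs_t <- observed$time_days[observed$dose_mg_kg == d]
      log(pmax(stats::approx(prof$time_days, prof$conc_ug_ml, obs_t)$y, 1e-12))
    }))
  }
  obs_log <- unlist(lapply(doses, function(d)
    log(observed$conc_ug_ml[observed$dose_mg_kg == d])))
  resid_fn <- function(par) pred_log(par) - obs_log
  fit <- minpack.lm::nls.lm(par = log(start), fn = resid_fn, control = control)
  if (fit$info %in% c(0, 5))
    stop(sprintf("TMDD fit did not converge (%s); best-so-far: kd=%.4g, r0=%.4g, kdeg=%.4g",
                 fit$message, exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3])))
  par <- stats::setNames(exp(fit$par), c("kd_fcrn", "r0", "kdeg_complex"))
  drug <- model_template$drug
  drug$kd_fcrn <- par[["kd_fcrn"]]
  drug$tmdd <- tmdd_parameters(tm0$kd_target, tm0$koff, tm0$ksyn,
                               par[["kdeg_complex"]], par[["r0"]])
  structure(list(par = par, fitted_drug = drug,
                 residual_sd = sqrt(fit$deviance / max(1, length(obs_log) - 3)),
                 n_obs = length(obs_log), dose_groups = doses,
                 convergence = fit$info, message = fit$message,
                 nls_lm = fit),
            class = "tmdd_fit")
}

#' @export
print.tmdd_fit <- function(x, ...) {
  cat("<tmdd_fit> weighted least squares on log concentrations\n")
  cat(sprintf("  dose groups: %s mg/kg; n = %d observations\n",
              paste(x$dose_groups, collapse = ", "), x$n_obs))
  cat(sprintf("  kd_fcrn = %.4g uM, r0 = %.4g uM, kdeg_complex = %.4g 1/day\n",
              x$par[["kd_fcrn"]], x$par[["r0"]], x$par[["kdeg_complex"]]))
  cat(sprintf("  residual SD (log scale) %.3g; %s\n", x$residual_sd, x$message))
  invisible(x)
}

#' @export
coef.tmdd_fit <- function(object, ...) object$par

#' @export
summary.tmdd_fit <- function(object, ...) {
  cat("Call: fit of {kd_fcrn, r0, kdeg_complex} to pooled dose groups\n")
  print(object)
  invisible(object)
}

#' @export
residuals.tmdd_fit <- function(object, ...) object$nls_lm$fvec
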