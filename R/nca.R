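# Non-compartmental analysis: AUC / AUMC moments, terminal-phase
# regression, clearance and steady-state volume.

#' Sampling grid for NCA of simulated bolus profiles
#'
#' Regular grid with logarithmic refinement immediately after dosing so that
#' the venous-pool mixing transient (time constant of seconds) is resolved;
#' without the refinement the first trapezoid interval overstates the AUC of
#' an intravenous bolus by a few percent.
#'
#' @param obs_days Observation window (days).
#' @param dt Regular step (days).
#' @return Increasing vector of times starting at 0.
#' @export
nca_times <- function(obs_days, dt = 0.25) {
  early <- c(1, 2, 5) * rep(10^(-4:-1), each = 3)
  sort(unique(c(0, early[early < dt], seq(dt, obs_days, by = dt))))
}

.nca_xy <- function(profile) {
  if (inherits(profile, "pk_profile") || is.data.frame(profile))
    list(t = profile$time_days, c = profile$conc_ug_ml)
  else stop("profile must be a pk_profile / data.frame with time_days, conc_ug_ml")
}

# interval contributions for AUC and AUMC; log rule on strictly decreasing
# positive intervals when method = "linlog", trapezoid otherwise
.nca_moments <- function(t, c, method) {
  t1 <- t[-length(t)]; t2 <- t[-1]
  c1 <- c[-length(c)]; c2 <- c[-1]
  dt <- t2 - t1
  lin_auc <- (c1 + c2) / 2 * dt
  lin_aumc <- (t1 * c1 + t2 * c2) / 2 * dt
  if (method == "linear") return(list(auc = lin_auc, aumc = lin_aumc))
  logint <- c2 < c1 & c2 > 0 & c1 > 0
  k <- rep(NA_real_, length(dt))
  k[logint] <- log(c1[logint] / c2[logint]) / dt[logint]
  auc <- lin_auc; aumc <- lin_aumc
  auc[logint] <- (c1[logint] - c2[logint]) / k[logint]
  aumc[logint] <- (t1[logint] * c1[logint] - t2[logint] * c2[logint]) / k[logint] +
    (c1[logint] - c2[logint]) / k[logint]^2
  list(auc = auc, aumc = aumc)
}

#' Area under a concentration-time curve
#'
#' Linear-up/log-down trapezoid by default; the log rule applies on strictly
#' decreasing, positive intervals.
#'
#' @param profile A `pk_profile` (or data.frame with `time_days`,
#'   `conc_ug_ml`).
#' @param t_start,t_end Integration window (defaults: full profile).  Window
#'   bounds must lie inside the observed time range; interior bounds are
#'   interpolated.
#' @param method `"linlog"` (default) or `"linear"`.
#' @return AUC over the window in ug day/ml.
#' @export
nca_auc <- function(profile, t_start = NULL, t_end = NULL,
                    method = c("linlog", "linear")) {
  method <- match.arg(method)
  xy <- .nca_xy(profile)
  t <- xy$t; c <- xy$c
  if (is.null(t_start)) t_start <- min(t)
  if (is.null(t_end)) t_end <- max(t)
  if (t_start < min(t) || t_end > max(t) || t_end <= t_start)
    stop("integration window outside the observed data")
  keep <- t >= t_start & t <= t_end
  tt <- t[keep]; cc <- c[keep]
  if (!(t_start %in% tt)) {
    tt <- c(t_start, tt); cc <- c(stats::approx(t, c, t_start)$y, cc)
  }
  if (!(t_end %in% tt)) {
    tt <- c(tt, t_end); cc <- c(cc, stats::approx(t, c, t_end)$y)
  }
  if (length(tt) < 2) stop("need at least 2 points in the window")
  sum(.nca_moments(tt, cc, method)$auc)
}

#' Terminal-phase log-linear regression
#'
#' Selects the terminal window automatically: among all suffixes of at least
#' 3 positive concentrations that start after Cmax, the window with the best
#' adjusted R-squared wins; ties go to the longer window.
#'
#' @param profile A `pk_profile`.
#' @param min_points Minimum window length (default 3).
#' @return A list with `lambda_z` (1/day), `t_half` (days), `r2_adjusted`,
#'   `n_points`, `window` (start/end times) and `intercept` (log scale).
#' @export
terminal_phase <- function(profile, min_points = 3) {
  xy <- .nca_xy(profile)
  pos <- xy$c > 0
  t <- xy$t[pos]; lc <- log(xy$c[pos])
  n <- length(t)
  imax <- which.max(lc)
  first_ok <- imax + 1L                   # window must exclude Cmax
  if (n - first_ok + 1L < min_points)
    stop("no acceptable terminal window: need >= 3 positive points after Cmax")
  # suffix regressions in O(n) via reverse cumulative sums
  rs <- function(v) rev(cumsum(rev(v)))
  S1 <- rs(rep(1, n)); St <- rs(t); Sy <- rs(lc)
  Stt <- rs(t^2); Sty <- rs(t * lc); Syy <- rs(lc^2)
  idx <- first_ok:(n - min_points + 1L)
  m <- S1[idx]
  sxx <- Stt[idx] - St[idx]^2 / m
  sxy <- Sty[idx] - St[idx] * Sy[idx] / m
  syy <- Syy[idx] - Sy[idx]^2 / m
  slope <- sxy / sxx
  r2 <- ifelse(syy > 0, sxy^2 / (sxx * syy), 1)
  adj <- 1 - (1 - r2) * (m - 1) / (m - 2)
  adj[slope >= 0] <- -Inf                 # terminal phase must decline
  if (all(!is.finite(adj))) stop("no declining terminal window found")
  best <- which(adj == max(adj, na.rm = TRUE))
  best <- best[1]                         # idx increasing = longer first
  i0 <- idx[best]
  lam <- -slope[best]
  # intercept a of lc ~ a + b t on the selected window
  a <- Sy[i0] / S1[i0] - slope[best] * St[i0] / S1[i0]
  list(lambda_z = lam, t_half = log(2) / lam,
       r2_adjusted = adj[best], n_points = as.integer(S1[i0]),
       window = c(t[i0], t[n]), intercept = a)
}

#' Non-compartmental parameters of a single-dose profile
#'
#' Combines [nca_auc()], [terminal_phase()] and AUMC moment analysis:
#' `AUC_inf = AUC_0-t + C_hat(t_last)/lambda_z` using the
#' regression-predicted last concentration, `CL = dose/AUC_inf`,
#' `MRT = AUMC_inf/AUC_inf` and `Vss = CL x MRT`.
#'
#' @param profile A `pk_profile` after a single IV dose.
#' @param dose_mg Administered dose in mg (default: from the profile
#'   metadata).
#' @param method AUC method.
#' @return An object of class `nca_result` with fields `auc_0_t`, `auc_inf`,
#'   `aumc_inf`, `lambda_z`, `t_half`, `cl` (ml/day), `vss` (ml), `mrt`
#'   (days), `extrapolated_fraction` (%), and the terminal-window report.
#' @export
nca_parameters <- function(profile, dose_mg = NULL,
                           method = c("linlog", "linear")) {
  method <- match.arg(method)
  if (is.null(dose_mg)) dose_mg <- attr(profile, "meta")$dose_mg
  stopifnot(!is.null(dose_mg), dose_mg > 0)
  xy <- .nca_xy(profile)
  term <- terminal_phase(profile)
  mom <- .nca_moments(xy$t, xy$c, method)
  auc_t <- sum(mom$auc); aumc_t <- sum(mom$aumc)
  t_last <- max(xy$t)
  c_hat <- exp(term$intercept - term$lambda_z * t_last)
  auc_inf <- auc_t + c_hat / term$lambda_z
  aumc_inf <- aumc_t + c_hat * t_last / term$lambda_z + c_hat / term$lambda_z^2
  cl <- dose_mg * 1000 / auc_inf
  mrt <- aumc_inf / auc_inf
  extr <- 100 * (1 - auc_t / auc_inf)
  structure(list(auc_0_t = auc_t, auc_inf = auc_inf, aumc_inf = aumc_inf,
                 lambda_z = term$lambda_z, t_half = term$t_half,
                 cl = cl, vss = cl * mrt, mrt = mrt,
                 extrapolated_fraction = extr,
                 extrapolation_flag = extr > 20,
                 terminal_window = term$window,
                 r2_adjusted = term$r2_adjusted,
                 n_terminal = term$n_points,
                 dose_mg = dose_mg),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>\n")
  cat(sprintf("  AUC_0-t %.4g, AUC_inf %.4g ug day/ml (extrapolated %.1f%%%s)\n",
              x$auc_0_t, x$auc_inf, x$extrapolated_fraction,
              if (x$extrapolation_flag) ", > 20% flag" else ""))
  cat(sprintf("  lambda_z %.4g 1/day (T1/2 %.3g d, window %.3g-%.3g d, n=%d, adj-R2 %.5f)\n",
              x$lambda_z, x$t_half, x$terminal_window[1], x$terminal_window[2],
              x$n_terminal, x$r2_adjusted))
  cat(sprintf("  CL %.4g ml/day, Vss %.4g ml, MRT %.3g d\n", x$cl, x$vss, x$mrt))
  invisible(x)
}
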