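# Whole-body antibody PBPK model: assembly, simulation, FcRn calibration.
#
# State layout (amounts in nmol):
#   1..9    organ vascular plasma
#   10..18  organ interstitial space
#   19..27  organ endosomal space (FcRn-bound and unbound drug partition
#           instantaneously at fixed free-FcRn concentration, so one state
#           per organ carries both; the bound/unbound split is algebraic)
#   28      venous plasma pool
#   29      arterial plasma pool
# With TMDD attached, free target and complex concentrations (uM) follow in
# each of the 20 extracellular compartments (9 plasma, 9 interstitial,
# venous, arterial): states 30..49 = R, 50..69 = C.
#
# Internal concentration unit: nmol/ml = uM, so FcRn and target
# dissociation constants in uM apply directly.  Reporting unit: ug/ml
# (1 nmol of a MW-kDa protein weighs MW ug).

.N_ORG <- 9L

#' Assemble a whole-body antibody PBPK model
#'
#' Couples a (possibly growing) physiology to a drug via organ-wise two-pore
#' transcapillary exchange, lymph return to the venous pool, interstitial
#' fluid recirculation, and endosomal uptake with FcRn-protected catabolism.
#'
#' @param trajectory A [make_growth_trajectory()] object.
#' @param drug A [drug_properties()] object.
#' @param endosomal An [endosomal_parameters()] object.
#' @param pores A [two_pore_parameters()] object.
#' @return An object of class `pbpk_model`.  Attach target-mediated
#'   disposition with [attach_tmdd()]; simulate with [simulate_pbpk()].
#' @export
pbpk_model <- function(trajectory, drug,
                       endosomal = endosomal_parameters(),
                       pores = two_pore_parameters()) {
  stopifnot(inherits(trajectory, "growth_trajectory"),
            inherits(drug, "drug_properties"),
            inherits(endosomal, "endosomal_parameters"),
            inherits(pores, "two_pore_parameters"))
  org <- .phys_tables()$organs
  pack <- .pbpk_pack_builder(trajectory)
  p0 <- pack(0)
  if (!all(vapply(p0, function(v) all(is.finite(unlist(v))) , TRUE)[
        c("vpl", "vis", "vendo", "q", "l", "rec", "vven", "vart")]))
    stop("non-finite physiology at simulation start; cannot assemble model")
  structure(list(trajectory = trajectory, drug = drug,
                 endosomal = endosomal, pores = pores,
                 organ = org$organ, i_lung = match("lung", org$organ),
                 pore_coefs = .two_pore_unit_coefs(pores, drug$hydrodynamic_radius),
                 tmdd = NULL,
                 pack = pack),
            class = "pbpk_model")
}

# fast physiology evaluator: simulation time (days) -> list of organ vectors
.pbpk_pack_builder <- function(trajectory) {
  org <- .phys_tables()$organs
  sx <- trajectory$start$sex
  sf <- .phys_splines(sx)
  ad <- .phys_adult_ref(sx, trajectory$endo_frac, trajectory$recirc_frac)
  massfrac <- org$mass_frac_bw; vascfrac <- org$vasc_frac_blood
  flowfrac <- org$flow_frac_co; lymphfrac <- org$lymph_frac_flow
  intfrac <- org$int_frac_vol
  i_lung <- match("lung", org$organ)
  endo_frac <- trajectory$endo_frac; recirc_frac <- trajectory$recirc_frac
  ws <- trajectory$weight_scale
  age0 <- trajectory$start$postnatal_age
  grow <- trajectory$growth_enabled
  age_max <- sf$range[2]
  function(t_days) {
    age <- if (grow) min(age0 + t_days / 365.25, age_max) else age0
    bw <- sf$bw(age) * ws; hct <- sf$hct(age); blood <- sf$blood(age) * ws
    co_pl <- sf$co(age) * ws * 1000 * 1440 * (1 - hct)
    ecw <- sf$ecw(age)
    vpl <- vascfrac * blood * (1 - hct)
    vorg <- massfrac * bw * 1000
    l_lung <- lymphfrac[i_lung] * co_pl
    q <- flowfrac * (co_pl - l_lung); q[i_lung] <- co_pl
    l <- lymphfrac * q
    list(bw = bw, vpl = vpl, vis = intfrac * vorg * ecw,
         vendo = endo_frac * vpl, q = q, l = l,
         rec = recirc_frac * ad$l * (vorg / ad$vorg)^(2 / 3),
         vven = 0.18 * blood * (1 - hct), vart = 0.06 * blood * (1 - hct))
  }
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s, start age %.3g y (%s), growth %s%s\n",
              x$drug$name, x$trajectory$start$postnatal_age,
              x$trajectory$start$sex,
              if (x$trajectory$growth_enabled) "on" else "off",
              if (is.null(x$tmdd)) "" else ", TMDD attached"))
  p <- x$pack(0)
  cat(sprintf("  BW %.2f kg; 9 organs + venous/arterial pools; %d states\n",
              p$bw, .pbpk_n_states(x)))
  invisible(x)
}

.pbpk_n_states <- function(model) {
  3L * .N_ORG + 2L + if (is.null(model$tmdd)) 0L else 2L * (2L * .N_ORG + 2L)
}

# Right-hand side closure for deSolve.  `inf_rate` (nmol/day into the venous
# pool) is read from the enclosing environment and set per dosing segment.
.pbpk_rhs_builder <- function(model, rhs_env) {
  n <- .N_ORG
  i_pl <- 1:n; i_is <- n + 1:n; i_en <- 2L * n + 1:n
  i_ven <- 3L * n + 1L; i_art <- 3L * n + 2L
  i_lung <- model$i_lung
  nonlung <- setdiff(1:n, i_lung)
  aH <- model$pore_coefs[["a"]]; bH <- model$pore_coefs[["b"]]
  en <- model$endosomal
  fu <- model$drug$kd_fcrn / (model$drug$kd_fcrn + en$free_fcrn)
  kup <- en$uptake_rate; krec <- en$recycling_rate; kclr <- en$clearance_rate
  tm <- model$tmdd
  nx <- 2L * n + 2L                      # extracellular compartments
  i_R <- 3L * n + 2L + 1:nx; i_C <- 3L * n + 2L + nx + 1:nx
  pack <- model$pack
  grow <- model$trajectory$growth_enabled
  p_fix <- pack(0)
  function(t, y, parms) {
    p <- if (grow) pack(t) else p_fix
    cpl <- y[i_pl] / p$vpl; cis <- y[i_is] / p$vis
    cven <- y[i_ven] / p$vven; cart <- y[i_art] / p$vart
    jnet <- p$l + p$rec
    jtp <- jnet * (aH * cpl - bH * cis)
    upl <- 0.5 * kup * p$vendo * cpl
    uis <- 0.5 * kup * p$vendo * cis
    recyc <- krec * (1 - fu) * y[i_en]
    degr <- kclr * fu * y[i_en]
    cin <- rep.int(cart, n); cin[i_lung] <- cven
    dpl <- p$q * cin - (p$q - p$l) * cpl - jtp - upl + 0.5 * recyc + p$rec * cis
    dis <- jtp - jnet * cis - uis + 0.5 * recyc
    den <- upl + uis - recyc - degr
    dven <- sum((p$q - p$l)[nonlung] * cpl[nonlung]) + sum(p$l * cis) -
      p$q[i_lung] * cven + rhs_env$inf_rate
    dart <- (p$q[i_lung] - p$l[i_lung]) * cpl[i_lung] - sum(p$q[nonlung]) * cart
    if (is.null(tm)) return(list(c(dpl, dis, den, dven, dart)))
    vx <- c(p$vpl, p$vis, p$vven, p$vart)
    D <- c(cpl, cis, cven, cart)
    R <- y[i_R]; C <- y[i_C]
    bind <- tm$kon * D * R; unb <- tm$koff_day * C
    dR <- tm$ksyn * (tm$r0 - R) - bind + unb
    dC <- bind - unb - tm$kdeg_complex * C
    dA <- (unb - bind) * vx
    dpl <- dpl + dA[1:n]; dis <- dis + dA[n + 1:n]
    dven <- dven + dA[2L * n + 1L]; dart <- dart + dA[2L * n + 2L]
    list(c(dpl, dis, den, dven, dart, dR, dC))
  }
}

#' Simulate an antibody PBPK model
#'
#' Integrates the whole-body system over a dosing regimen with a stiff
#' solver; doses are intravenous into the venous pool, with absolute amounts
#' computed from the body weight at each dose time (so later doses grow with
#' a growth-enabled trajectory).
#'
#' @param model A [pbpk_model()], optionally with TMDD attached.
#' @param regimen A [dose_regimen()].
#' @param times Output times in days (strictly increasing, >= 0).
#' @param rtol,atol Solver tolerances (state unit nmol).
#' @return A `pk_profile`: data.frame with `time_days` and `conc_ug_ml`
#'   (venous plasma), with dose/individual metadata in `attr(, "meta")` and,
#'   in `attr(, "state")`, the full state matrix at the output times.
#' @export
simulate_pbpk <- function(model, regimen, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "pbpk_model"), inherits(regimen, "dose_regimen"))
  times <- sort(unique(as.numeric(times)))
  stopifnot(all(times >= 0), length(times) >= 1)
  ns <- .pbpk_n_states(model)
  y <- numeric(ns)
  if (!is.null(model$tmdd)) {
    nx <- 2L * .N_ORG + 2L
    y[3L * .N_ORG + 2L + 1:nx] <- model$tmdd$r0
  }
  mw <- model$drug$molecular_weight
  pack <- model$pack
  dose_nmol <- vapply(seq_len(nrow(regimen)), function(k) {
    regimen$amount_per_kg[k] * pack(regimen$time[k])$bw * 1000 / mw
  }, 0)
  tmax <- max(times, regimen$time + regimen$duration)
  bounds <- sort(unique(c(0, regimen$time, regimen$time + regimen$duration, tmax)))
  bounds <- bounds[bounds <= tmax]
  if (bounds[length(bounds)] < tmax) bounds <- c(bounds, tmax)
  rhs_env <- new.env(parent = emptyenv()); rhs_env$inf_rate <- 0
  rhs <- .pbpk_rhs_builder(model, rhs_env)
  i_ven <- 3L * .N_ORG + 1L
  out_t <- numeric(0); out_y <- NULL
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    bol <- which(regimen$time == a & regimen$duration == 0)
    if (length(bol)) y[i_ven] <- y[i_ven] + sum(dose_nmol[bol])
    act <- which(regimen$duration > 0 & regimen$time <= a &
                   regimen$time + regimen$duration > a)
    rhs_env$inf_rate <- if (length(act))
      sum(dose_nmol[act] / regimen$duration[act]) else 0
    seg_t <- sort(unique(c(a, times[times > a & times <= b], b)))
    if (length(seg_t) < 2) seg_t <- c(a, b)
    sol <- deSolve::lsoda(y, seg_t, rhs, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("PBPK solver failure in segment [%g, %g] d; final state norm %.3g",
                   a, b, sum(abs(y))))
    keep <- sol[, 1] %in% times & sol[, 1] < b
    if (a == 0 && 0 %in% times) keep[1] <- TRUE
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
    y <- sol[nrow(sol), -1]
    if (b %in% times && k == length(bounds) - 1L) {
      out_t <- c(out_t, b); out_y <- rbind(out_y, y)
    }
  }
  ord <- order(out_t); out_t <- out_t[ord]
  out_y <- out_y[ord, , drop = FALSE]
  dup <- duplicated(out_t)
  out_t <- out_t[!dup]; out_y <- out_y[!dup, , drop = FALSE]
  vven <- vapply(out_t, function(t) pack(t)$vven, 0)
  conc <- pmax(out_y[, i_ven] / vven, 0) * mw
  pk_profile(out_t, conc,
             meta = list(drug = model$drug$name,
                         dose_mg_kg = regimen$amount_per_kg[1],
                         regimen = as.data.frame(regimen),
                         growth_enabled = model$trajectory$growth_enabled,
                         age_y = model$trajectory$start$postnatal_age,
                         sex = model$trajectory$start$sex,
                         bw_kg = pack(0)$bw,
                         dose_mg = dose_nmol[1] * mw / 1000),
             state = out_y)
}

#' @rdname simulate_pbpk
#' @param object A `pbpk_model` (S3 `simulate` method).
#' @param nsim,seed Accepted for generic compatibility; the model is
#'   deterministic, so `nsim` must be 1 and `seed` is ignored.
#' @param ... Passed on to `simulate_pbpk()`.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL, ...) {
  stopifnot(nsim == 1)
  simulate_pbpk(object, ...)
}

#' Concentration-time profile container
#'
#' @param time_days Strictly increasing times (days).
#' @param conc_ug_ml Plasma concentrations (ug/ml, >= 0).
#' @param meta Named list of metadata (dose, individual, growth flag...).
#' @param state Optional matrix of model states at `time_days`.
#' @return A data.frame of class `pk_profile`.
#' @export
pk_profile <- function(time_days, conc_ug_ml, meta = list(), state = NULL) {
  stopifnot(all(diff(time_days) > 0), all(conc_ug_ml >= 0),
            length(time_days) == length(conc_ug_ml))
  structure(data.frame(time_days = time_days, conc_ug_ml = conc_ug_ml),
            meta = meta, state = state,
            class = c("pk_profile", "data.frame"))
}

#' @export
print.pk_profile <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<pk_profile> %d points over %g d%s\n", nrow(x),
              max(x$time_days),
              if (!is.null(m$drug))
                sprintf("; %s %g mg/kg, age %.3g y, growth %s", m$drug,
                        m$dose_mg_kg, m$age_y,
                        if (isTRUE(m$growth_enabled)) "on" else "off")
              else ""))
  cat(sprintf("  Cmax %.3g ug/ml, Clast %.3g ug/ml\n",
              max(x$conc_ug_ml), x$conc_ug_ml[nrow(x)]))
  invisible(x)
}

#' @export
plot.pk_profile <- function(x, ..., log = "y", xlab = "time [days]",
                            ylab = "plasma concentration [ug/ml]",
                            type = "l") {
  y <- x$conc_ug_ml
  if (grepl("y", log)) y[y <= 0] <- NA
  graphics::plot(x$time_days, y, log = log, xlab = xlab, ylab = ylab,
                 type = type, ...)
  invisible(x)
}

# single-dose NCA clearance of a model (ml/day); workhorse for calibration
# and the age sweeps
.pbpk_nca <- function(model, dose_mg_kg = 1, days = 150, dt = 0.5,
                      rtol = 1e-8, atol = 1e-10) {
  prof <- simulate_pbpk(model, dose_regimen(dose_mg_kg),
                        times = nca_times(days, dt), rtol = rtol, atol = atol)
  nca_parameters(prof, dose_mg = attr(prof, "meta")$dose_mg)
}

# replace the drug's FcRn affinity, keeping precomputed pore coefficients
.pbpk_set_kd <- function(model, kd) {
  model$drug$kd_fcrn <- kd
  model
}

#' Calibrate the FcRn dissociation constant to a target adult clearance
#'
#' Root-finds `Kd(FcRn)` so that the NCA clearance of a single-dose
#' simulation matches `target_cl`.  Higher `Kd` (weaker FcRn protection)
#' gives higher clearance, so the root is unique.
#'
#' @param model A `pbpk_model` (typically adult physiology); any attached
#'   TMDD stays in place during calibration.
#' @param target_cl Target clearance in ml/day.
#' @param dose_mg_kg Dose used for the calibration simulations (relevant only
#'   with TMDD attached; default 10 mg/kg, a therapeutic dose).
#' @param interval Search interval for `Kd` in uM.
#' @param tol Relative clearance tolerance (default 1e-3, i.e. 0.1%).
#' @param days,dt Simulation horizon and grid used for the NCA.
#' @return The calibrated `Kd` (uM), with the achieved clearance in
#'   `attr(, "cl")`.
#' @export
calibrate_fcrn_kd <- function(model, target_cl, dose_mg_kg = 10,
                              interval = c(1e-4, 1e3), tol = 1e-3,
                              days = 150, dt = 0.5) {
  stopifnot(inherits(model, "pbpk_model"), target_cl > 0)
  cl_at <- function(kd)
    .pbpk_nca(.pbpk_set_kd(model, kd), dose_mg_kg, days, dt)$cl
  cl_lo <- cl_at(interval[1]); cl_hi <- cl_at(interval[2])
  if (target_cl < cl_lo || target_cl > cl_hi)
    stop(sprintf(paste0("target clearance %.4g ml/day outside the attainable ",
                        "interval [%.4g, %.4g] ml/day for Kd in [%g, %g] uM"),
                 target_cl, cl_lo, cl_hi, interval[1], interval[2]))
  f <- function(lk) cl_at(10^lk) - target_cl
  r <- stats::uniroot(f, log10(interval), tol = 1e-5)
  kd <- 10^r$root
  cl <- cl_at(kd)
  if (abs(cl - target_cl) / target_cl > tol)
    stop(sprintf("calibration did not reach %.1f%% tolerance (CL %.4g vs %.4g)",
                 100 * tol, cl, target_cl))
  structure(kd, cl = cl)
}
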