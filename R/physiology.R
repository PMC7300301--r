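# Age- and sex-resolved reference physiology for the reduced whole-body model.
#
# All quantities derive from two embedded CSV tables (inst/extdata): an
# anthropometry table (body weight, height, blood volume, hematocrit, cardiac
# output, extracellular-water expansion) with age nodes from term birth to
# 80 y, and an organ table with age-independent fractions for the 9 lumped
# organs.  Values between age nodes come from monotone piecewise-cubic
# interpolation so that growth trajectories never overshoot the table nodes.

.pedmabpk_env <- new.env(parent = emptyenv())

.phys_tables <- function() {
  if (is.null(.pedmabpk_env$anthro)) {
    .pedmabpk_env$anthro <- utils::read.csv(
      system.file("extdata", "anthropometry.csv", package = "pedmabpk"),
      stringsAsFactors = FALSE)
    .pedmabpk_env$organs <- utils::read.csv(
      system.file("extdata", "organs.csv", package = "pedmabpk"),
      stringsAsFactors = FALSE)
  }
  list(anthro = .pedmabpk_env$anthro, organs = .pedmabpk_env$organs)
}

# Monotone (Fritsch-Carlson) interpolators per sex, built once and cached.
.phys_splines <- function(sex) {
  key <- paste0("splines_", sex)
  sf <- .pedmabpk_env[[key]]
  if (!is.null(sf)) return(sf)
  tab <- .phys_tables()$anthro
  tab <- tab[tab$sex == sex, ]
  tab <- tab[order(tab$age_y), ]
  mk <- function(col) stats::splinefun(tab$age_y, tab[[col]], method = "monoH.FC")
  sf <- list(
    bw    = mk("bw_kg"),
    ht    = mk("ht_cm"),
    blood = mk("blood_ml"),
    hct   = mk("hct"),
    co    = mk("co_l_min"),
    ecw   = mk("ecw_scale"),
    range = range(tab$age_y))
  .pedmabpk_env[[key]] <- sf
  sf
}

#' Specify an individual's age and sex
#'
#' @param postnatal_age Postnatal age in years (>= 0).
#' @param gestational_age Gestational age at birth in weeks; default 40
#'   (term).  Only used for PAGE bookkeeping (the maturation covariate of the
#'   palivizumab population-PK model); the embedded physiology tables describe
#'   term-born individuals.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `age_spec`.
#' @examples
#' a <- age_spec(0.5)
#' page_weeks(a)
#' @export
age_spec <- function(postnatal_age, gestational_age = 40, sex = c("male", "female")) {
  sex <- match.arg(sex)
  stopifnot(is.numeric(postnatal_age), length(postnatal_age) == 1,
            is.finite(postnatal_age), postnatal_age >= 0)
  if (gestational_age < 22 || gestational_age > 44)
    stop("gestational_age must lie in [22, 44] weeks")
  structure(list(postnatal_age = postnatal_age,
                 gestational_age = gestational_age,
                 sex = sex),
            class = "age_spec")
}

#' @export
print.age_spec <- function(x, ...) {
  cat(sprintf("<age_spec> %s, postnatal age %.3g y, gestational age %g wk (PAGE %.1f wk)\n",
              x$sex, x$postnatal_age, x$gestational_age, page_weeks(x)))
  invisible(x)
}

# 1 month = 365.25/12 days; PAGE conversions are centralized here.
.DAYS_PER_MONTH <- 365.25 / 12
.WEEKS_PER_YEAR <- 365.25 / 7

#' PAGE (gestational + postnatal age) in weeks
#' @param age An `age_spec`.
#' @param at_days Additional simulation time in days to add to the postnatal
#'   age (default 0).
#' @return PAGE in weeks.
#' @export
page_weeks <- function(age, at_days = 0) {
  age$gestational_age + (age$postnatal_age + at_days / 365.25) * .WEEKS_PER_YEAR
}

#' PAGE in months
#' @inheritParams page_weeks
#' @return PAGE in months (1 month = 365.25/12 days).
#' @export
page_months <- function(age, at_days = 0) {
  page_weeks(age, at_days) * 7 / .DAYS_PER_MONTH
}

# Fast numeric physiology used inside ODE right-hand sides: plain vectors, no
# data.frame overhead.  endo_frac is the endosomal/vascular volume ratio;
# recirc_frac the recirculation/lymph flow ratio at the adult reference.
.phys_numeric <- function(age_y, sex, endo_frac = 0.005, recirc_frac = 0.5,
                          weight_scale = 1) {
  sf <- .phys_splines(sex)
  org <- .phys_tables()$organs
  bw    <- sf$bw(age_y) * weight_scale
  hct   <- sf$hct(age_y)
  blood <- sf$blood(age_y) * weight_scale
  co_pl <- sf$co(age_y) * weight_scale * 1000 * 1440 * (1 - hct)  # ml plasma/day
  ecw   <- sf$ecw(age_y)

  vpl  <- org$vasc_frac_blood * blood * (1 - hct)
  vorg <- org$mass_frac_bw * bw * 1000
  vis  <- org$int_frac_vol * vorg * ecw
  vendo <- endo_frac * vpl

  # lung carries total cardiac plasma output; systemic organs share what the
  # lung passes on after its (tiny) lymph drainage
  q_lung <- co_pl
  l_lung <- org$lymph_frac_flow[org$organ == "lung"] * q_lung
  q <- ifelse(org$organ == "lung", q_lung, org$flow_frac_co * (co_pl - l_lung))
  l <- org$lymph_frac_flow * q

  # recirculation: fraction of the adult lymph flow, scaled between ages with
  # an organ-volume^(2/3) allometric factor
  ad <- .phys_adult_ref(sex, endo_frac, recirc_frac)
  rec <- recirc_frac * ad$l * (vorg / ad$vorg)^(2 / 3)

  list(age_y = age_y, bw = bw, ht = sf$ht(age_y), hct = hct,
       blood = blood, co_plasma = co_pl, ecw = ecw,
       organ = org$organ, vpl = vpl, vorg = vorg, vis = vis, vendo = vendo,
       q = q, l = l, rec = rec,
       vven = 0.18 * blood * (1 - hct),
       vart = 0.06 * blood * (1 - hct))
}

# adult (35 y) per-organ lymph flows and organ volumes, cached per sex
.phys_adult_ref <- function(sex, endo_frac, recirc_frac) {
  key <- paste0("adultref_", sex)
  ref <- .pedmabpk_env[[key]]
  if (!is.null(ref)) return(ref)
  sf <- .phys_tables()$organs
  sp <- .phys_splines(sex)
  bw <- sp$bw(35); hct <- sp$hct(35)
  co_pl <- sp$co(35) * 1000 * 1440 * (1 - hct)
  l_lung <- sf$lymph_frac_flow[sf$organ == "lung"] * co_pl
  q <- ifelse(sf$organ == "lung", co_pl, sf$flow_frac_co * (co_pl - l_lung))
  ref <- list(l = sf$lymph_frac_flow * q, vorg = sf$mass_frac_bw * bw * 1000)
  .pedmabpk_env[[key]] <- ref
  ref
}

#' Build a reference individual's physiology at one age
#'
#' Constructs the full organ-level snapshot (plasma, interstitial and
#' endosomal volumes; plasma, lymph and recirculation flows) for a mean
#' reference individual of the given age and sex, from the embedded
#' reference tables.
#'
#' @param age An [age_spec()].
#' @param endo_frac Endosomal volume as a fraction of the organ vascular
#'   plasma volume (default 0.005).  The absolute value is a free scale that
#'   is absorbed by FcRn-affinity calibration.
#' @param recirc_frac Recirculation flow as a fraction of the organ lymph flow
#'   at the adult reference (default 0.5).
#' @param weight_override Optional body weight (kg).  When given, body weight
#'   and all mass-proportional quantities (organ volumes, blood volume,
#'   cardiac output) are rescaled by `weight_override / table weight`; height
#'   is left unchanged.  Intended for cohorts (e.g. chronically ill children)
#'   whose weights fall below the reference medians.
#' @return An object of class `physiology_snapshot`: body-level scalars plus
#'   a per-organ `data.frame` (`organs`) with volumes in ml and flows in
#'   ml/day.
#' @examples
#' snap <- build_reference_physiology(age_spec(35))
#' snap$body_weight
#' @export
build_reference_physiology <- function(age, endo_frac = 0.005,
                                       recirc_frac = 0.5,
                                       weight_override = NULL) {
  stopifnot(inherits(age, "age_spec"))
  rng <- .phys_splines(age$sex)$range
  if (age$postnatal_age < rng[1] || age$postnatal_age > rng[2])
    stop(sprintf("age %.3g y outside the supported range [%g, %g] y",
                 age$postnatal_age, rng[1], rng[2]))
  wscale <- 1
  if (!is.null(weight_override)) {
    stopifnot(weight_override > 0)
    wscale <- weight_override / .phys_splines(age$sex)$bw(age$postnatal_age)
  }
  p <- .phys_numeric(age$postnatal_age, age$sex, endo_frac, recirc_frac, wscale)
  organs <- data.frame(
    organ = p$organ,
    plasma_volume = p$vpl,
    interstitial_volume = p$vis,
    endosomal_volume = p$vendo,
    plasma_flow = p$q,
    lymph_flow = p$l,
    recirculation_flow = p$rec,
    stringsAsFactors = FALSE)
  structure(list(age = age,
                 body_weight = p$bw,
                 body_height = p$ht,
                 hematocrit = p$hct,
                 blood_volume = p$blood,
                 cardiac_output_plasma = p$co_plasma,
                 venous_plasma = p$vven,
                 arterial_plasma = p$vart,
                 organs = organs,
                 endo_frac = endo_frac,
                 recirc_frac = recirc_frac,
                 weight_scale = wscale),
            class = "physiology_snapshot")
}

#' @export
print.physiology_snapshot <- function(x, ...) {
  cat(sprintf("<physiology_snapshot> %s, %.3g y: BW %.2f kg, height %.0f cm, Hct %.2f\n",
              x$age$sex, x$age$postnatal_age, x$body_weight, x$body_height,
              x$hematocrit))
  cat(sprintf("  plasma %.0f ml (venous %.0f, arterial %.0f), interstitial %.0f ml, endosomal %.2f ml\n",
              sum(x$organs$plasma_volume) + x$venous_plasma + x$arterial_plasma,
              x$venous_plasma, x$arterial_plasma,
              sum(x$organs$interstitial_volume), sum(x$organs$endosomal_volume)))
  cat(sprintf("  cardiac plasma output %.0f ml/day, total lymph %.0f ml/day\n",
              x$cardiac_output_plasma, sum(x$organs$lymph_flow)))
  invisible(x)
}

#' Growth trajectory for use during simulation
#'
#' Maps simulation time (days) to a physiology snapshot.  With
#' `growth_enabled = FALSE` the snapshot is frozen at the starting age; with
#' `TRUE` it is re-evaluated at `age + t`, so body weight and all volumes and
#' flows grow continuously (monotone interpolation between table nodes)
#' along the simulation.
#'
#' @inheritParams build_reference_physiology
#' @param growth_enabled Logical.
#' @return An object of class `growth_trajectory` with elements
#'   `snapshot(t_days)`, `age_at(t_days)` and the starting `age`.
#' @export
make_growth_trajectory <- function(age, growth_enabled = FALSE,
                                   endo_frac = 0.005, recirc_frac = 0.5,
                                   weight_override = NULL) {
  stopifnot(inherits(age, "age_spec"), is.logical(growth_enabled))
  base <- build_reference_physiology(age, endo_frac, recirc_frac, weight_override)
  snapshot <- if (growth_enabled) {
    function(t_days) {
      a2 <- age
      a2$postnatal_age <- age$postnatal_age + t_days / 365.25
      build_reference_physiology(a2, endo_frac, recirc_frac,
                                 if (!is.null(weight_override))
                                   weight_override * .phys_splines(age$sex)$bw(a2$postnatal_age) /
                                     .phys_splines(age$sex)$bw(age$postnatal_age)
                                 else NULL)
    }
  } else {
    function(t_days) base
  }
  structure(list(start = age, growth_enabled = growth_enabled,
                 endo_frac = endo_frac, recirc_frac = recirc_frac,
                 weight_scale = base$weight_scale,
                 snapshot = snapshot,
                 age_at = function(t_days)
                   age$postnatal_age + if (growth_enabled) t_days / 365.25 else 0),
            class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("<growth_trajectory> start %.3g y (%s), growth %s\n",
              x$start$postnatal_age, x$start$sex,
              if (x$growth_enabled) "enabled" else "disabled"))
  invisible(x)
}

#' Piecewise body-weight growth rule of the palivizumab population-PK model
#'
#' Updates body weight over a PAGE interval using the published piecewise
#' rates: 0.89 kg/month below 13 months PAGE and 0.24 kg/month at or above,
#' split exactly at 13 months when the interval straddles the breakpoint.
#'
#' @param page_prev,page_now PAGE (gestational + postnatal age) in months;
#'   `page_now >= page_prev`.
#' @param bw_prev Body weight (kg) at `page_prev`.
#' @return Body weight (kg) at `page_now`.
#' @examples
#' poppk_bodyweight_update(10, 12, 7)   # 7 + 0.89*2
#' poppk_bodyweight_update(12, 14, 8)   # straddles 13 months
#' @export
poppk_bodyweight_update <- function(page_prev, page_now, bw_prev) {
  stopifnot(bw_prev > 0)
  if (page_now < page_prev) stop("page_now must be >= page_prev")
  if (page_now < 13) {
    bw_prev + 0.89 * (page_now - page_prev)
  } else if (page_prev >= 13) {
    bw_prev + 0.24 * (page_now - page_prev)
  } else {
    bw_prev + 0.89 * (13 - page_prev) + 0.24 * (page_now - 13)
  }
}
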