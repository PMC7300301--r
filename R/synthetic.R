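# Seeded synthetic "observed" datasets emulating the source clinical study
# designs (dose groups, ages, sampling schedules), simulated from the popPK
# or PBPK models with residual error.  These stand in for the digitized
# clinical profiles, which are not redistributable.

#' Residual-error model for synthetic observations
#'
#' @param proportional_cv Proportional error coefficient of variation
#'   (fraction, default 0.2 -- typical of mAb immunoassays).
#' @param additive_sd Additive error SD in ug/ml (default 0).
#' @param lloq Lower limit of quantification in ug/ml; observations below it
#'   are flagged as censored (default 0 = off).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(proportional_cv = 0.2, additive_sd = 0, lloq = 0,
                        seed = NULL) {
  stopifnot(proportional_cv >= 0, additive_sd >= 0, lloq >= 0)
  structure(list(proportional_cv = proportional_cv, additive_sd = additive_sd,
                 lloq = lloq, seed = seed),
            class = "noise_model")
}

.default_sampling_days <- c(0.25, 1, 2, 7, 14, 21, 30, 60)

#' Study design descriptor
#'
#' @param label Design label.
#' @param drug `"palivizumab"` or `"bevacizumab"`.
#' @param dose_groups Doses in mg/kg.
#' @param n_per_group Individuals per dose group.
#' @param age_mean_y,age_sd_y Per-group age mean and SD in years (recycled).
#' @param age_range_y Truncation range for sampled ages.
#' @param sampling_days Nominal sampling times (days, increasing).
#' @param population `"pediatric"` or `"adult"`.
#' @param cns_tumor CNS-tumor covariate flag.
#' @return An object of class `study_design`.
#' @export
study_design <- function(label, drug, dose_groups, n_per_group,
                         age_mean_y, age_sd_y, age_range_y,
                         sampling_days = .default_sampling_days,
                         population = c("pediatric", "adult"),
                         cns_tumor = FALSE) {
  population <- match.arg(population)
  stopifnot(all(dose_groups > 0), all(diff(sampling_days) > 0),
            length(n_per_group) == length(dose_groups))
  structure(list(label = label, drug = drug, dose_groups = dose_groups,
                 n_per_group = n_per_group,
                 age_mean_y = rep_len(age_mean_y, length(dose_groups)),
                 age_sd_y = rep_len(age_sd_y, length(dose_groups)),
                 age_range_y = age_range_y,
                 sampling_days = sampling_days,
                 population = population, cns_tumor = cns_tumor),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %s (%s, %s): doses {%s} mg/kg, n = {%s}\n",
              x$label, x$drug, x$population,
              paste(x$dose_groups, collapse = ", "),
              paste(x$n_per_group, collapse = ", ")))
  cat(sprintf("  ages %s y (range %g-%g), sampling days %s\n",
              paste(sprintf("%.2g+/-%.2g", x$age_mean_y, x$age_sd_y),
                    collapse = ", "),
              x$age_range_y[1], x$age_range_y[2],
              paste(x$sampling_days, collapse = ", ")))
  invisible(x)
}

#' Built-in emulations of the five source study designs
#'
#' Dose groups, group sizes and age summaries follow the published study
#' table: the palivizumab phase I/II study in premature infants / infants
#' with bronchopulmonary dysplasia (3/10/15 mg/kg), the palivizumab study in
#' children with RSV infection (5/15 mg/kg), the adult bevacizumab phase I
#' study (0.1-10 mg/kg in 5 dose groups), the pediatric bevacizumab phase I
#' study, and the pediatric bevacizumab population-PK pooling (5/15 mg/kg).
#' Sampling schedules are nominal defaults (the exact printed schedules are
#' only partially inferable) and configurable via [study_design()].
#'
#' @return A named list of five [study_design()] objects.
#' @export
builtin_designs <- function() {
  mo <- 1 / 12
  list(
    palivizumab_bpd = study_design(
      "palivizumab phase I/II, premature/BPD infants", "palivizumab",
      dose_groups = c(3, 10, 15), n_per_group = c(10, 10, 22),
      age_mean_y = c(6.9, 7.39, 8.19) * mo, age_sd_y = c(1.3, 2, 1.7) * mo,
      age_range_y = c(0.1, 2)),
    palivizumab_rsv = study_design(
      "palivizumab phase I/II, children with RSV infection", "palivizumab",
      dose_groups = c(5, 15), n_per_group = c(8, 22),
      age_mean_y = c(1.5, 5.2) * mo, age_sd_y = c(0.4, 0.9) * mo,
      age_range_y = c(0.05, 2), sampling_days = c(0.25, 1, 2, 7, 14, 21, 30)),
    bevacizumab_adult = study_design(
      "bevacizumab phase I, adult cancer patients", "bevacizumab",
      dose_groups = c(0.1, 0.3, 1, 3, 10), n_per_group = rep(5L, 5),
      age_mean_y = 50, age_sd_y = 12, age_range_y = c(21, 75),
      sampling_days = c(0.04, 0.25, 1, 2, 4, 7, 14, 21, 28, 42, 70),
      population = "adult"),
    bevacizumab_ped_phase1 = study_design(
      "bevacizumab phase I, pediatric cancer patients", "bevacizumab",
      dose_groups = c(5, 15), n_per_group = c(4, 4),
      age_mean_y = 13, age_sd_y = 5, age_range_y = c(1, 21),
      cns_tumor = TRUE),
    bevacizumab_ped_poppk = study_design(
      "bevacizumab pediatric population-PK pooling", "bevacizumab",
      dose_groups = c(5, 15), n_per_group = c(76, 76),
      age_mean_y = 10.8, age_sd_y = 5, age_range_y = c(0.5, 21)))
}

# truncated-normal ages via rejection (vectorized enough at study sizes)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulator factories for [generate_observed()]
#'
#' `poppk_simulator()` simulates from a published two-compartment
#' population-PK model; `pbpk_simulator()` from a PBPK model built per
#' individual.
#'
#' @param drug For `poppk_simulator`, `"palivizumab"` or `"bevacizumab"`;
#'   for `pbpk_simulator`, a [drug_properties()] object.
#' @param growth Growth during simulation.
#' @param ... Extra arguments to [pbpk_model()] ([endosomal_parameters()],
#'   [two_pore_parameters()]).
#' @return A function `f(age_y, sex, cns_tumor, dose_mg_kg, times)`
#'   returning a `pk_profile`.
#' @export
poppk_simulator <- function(drug, growth = FALSE) {
  force(drug); force(growth)
  function(age_y, sex, cns_tumor, dose_mg_kg, times) {
    asp <- age_spec(age_y, sex = sex)
    bw <- build_reference_physiology(asp)$body_weight
    cov <- covariate_set(bw, page_weeks = page_weeks(asp), sex = sex,
                         cns_tumor = cns_tumor, age_y = age_y)
    simulate_poppk(drug, cov, dose_regimen(dose_mg_kg), times, growth = growth)
  }
}

#' @rdname poppk_simulator
#' @export
pbpk_simulator <- function(drug, growth = FALSE, ...) {
  force(drug); force(growth)
  function(age_y, sex, cns_tumor, dose_mg_kg, times) {
    traj <- make_growth_trajectory(age_spec(age_y, sex = sex),
                                   growth_enabled = growth)
    m <- pbpk_model(traj, drug, ...)
    if (!is.null(drug$tmdd)) m <- attach_tmdd(m)
    simulate_pbpk(m, dose_regimen(dose_mg_kg), times)
  }
}

#' Generate a synthetic observed dataset from a study design
#'
#' Draws individual ages from the design's truncated-normal summaries,
#' simulates every individual with `simulator`, and applies the residual
#' error model (proportional + additive, censoring below LLOQ).  The
#' noise-free predictions are retained so that parameter-recovery analyses
#' can compare against truth.
#'
#' @param design A [study_design()].
#' @param simulator A function from [poppk_simulator()] /
#'   [pbpk_simulator()].
#' @param noise A [noise_model()]; its seed makes the dataset reproducible.
#' @param sex Sex assigned to the virtual individuals.
#' @return A data.frame of class `observed_dataset` with columns `id`,
#'   `time_days`, `conc_ug_ml`, `pred_ug_ml` (noise-free truth),
#'   `dose_mg_kg`, `age_y`, `bw_kg`, `censored`.
#' @export
generate_observed <- function(design, simulator, noise = noise_model(),
                              sex = "male") {
  stopifnot(inherits(design, "study_design"), is.function(simulator),
            inherits(noise, "noise_model"))
  if (!is.null(noise$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
  }
  times <- design$sampling_days
  rows <- list(); id <- 0L
  for (g in seq_along(design$dose_groups)) {
    dose <- design$dose_groups[g]
    ages <- .rtruncnorm(design$n_per_group[g], design$age_mean_y[g],
                        design$age_sd_y[g], design$age_range_y[1],
                        design$age_range_y[2])
    for (a in ages) {
      id <- id + 1L
      prof <- simulator(a, sex, design$cns_tumor, dose, times)
      pred <- stats::approx(prof$time_days, prof$conc_ug_ml, times)$y
      eps_p <- stats::rnorm(length(times), 0, noise$proportional_cv)
      eps_a <- if (noise$additive_sd > 0)
        stats::rnorm(length(times), 0, noise$additive_sd) else 0
      obs <- pred * (1 + eps_p) + eps_a
      rows[[id]] <- data.frame(
        id = id, time_days = times, conc_ug_ml = obs, pred_ug_ml = pred,
        dose_mg_kg = dose, age_y = a,
        bw_kg = attr(prof, "meta")$bw_kg,
        censored = obs < noise$lloq)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, design = design$label, noise = noise,
            class = c("observed_dataset", "data.frame"))
}
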