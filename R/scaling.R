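# Age-sweep evaluation pipeline: body-weight-normalized and weight-adjusted
# clearances, relative-to-adult scaling curves, effective allometric
# exponents, and cross-model comparison tables.

.DEFAULT_AGES <- c(0, 0.25, 0.5, 1, 2, 5, 10, 15, 35)

#' Sweep ages and evaluate a model by NCA
#'
#' Simulates a single IV dose at each age for one model family, runs NCA on
#' each profile, and tabulates clearance (absolute, per kg, and
#' weight-adjusted `CL/(BW/70)^0.75`), steady-state volume and terminal
#' half-life.  Body weights at all ages come from the embedded reference
#' physiology so that all model families are compared on identical
#' individuals.
#'
#' @param drug A [drug_properties()] (used by the PBPK family; its name
#'   labels the rows).
#' @param model_kind One of `"pbpk"`, `"poppk_palivizumab"`,
#'   `"poppk_bevacizumab"`, `"allometric_0.75"`, `"allometric_1.0"`.
#' @param ages Age grid in years; must contain the adult reference age.
#' @param dose_per_kg Dose in mg/kg (default 10).
#' @param growth Enable growth during simulation.
#' @param sex Sex of the virtual individuals.
#' @param obs_days,dt Observation window (days) and sampling step for the
#'   simulated profiles.
#' @param adult_age Adult reference age (default 35 y).
#' @param endosomal,pores PBPK submodel parameters.
#' @param cl_anchor,vss_anchor Adult anchors (ml/day, ml) for the pure
#'   allometric reference families.
#' @return A data.frame of class `age_sweep` with one row per age.
#' @export
age_sweep <- function(drug, model_kind = c("pbpk", "poppk_palivizumab",
                                           "poppk_bevacizumab",
                                           "allometric_0.75", "allometric_1.0"),
                      ages = .DEFAULT_AGES, dose_per_kg = 10, growth = FALSE,
                      sex = "male", obs_days = 70, dt = 0.25, adult_age = 35,
                      endosomal = endosomal_parameters(),
                      pores = two_pore_parameters(),
                      cl_anchor = 198, vss_anchor = 6320) {
  model_kind <- match.arg(model_kind)
  if (!adult_age %in% ages)
    stop("the age grid must include the adult reference age")
  times <- nca_times(obs_days, dt)
  rows <- lapply(ages, function(a) {
    asp <- age_spec(a, sex = sex)
    bw <- build_reference_physiology(asp)$body_weight
    w70 <- bw / 70
    if (model_kind == "pbpk") {
      traj <- make_growth_trajectory(asp, growth_enabled = growth,
                                     endo_frac = endosomal_frac_default(),
                                     recirc_frac = 0.5)
      m <- pbpk_model(traj, drug, endosomal, pores)
      if (!is.null(drug$tmdd)) m <- attach_tmdd(m)
      prof <- simulate_pbpk(m, dose_regimen(dose_per_kg), times)
      res <- nca_parameters(prof)
    } else if (model_kind %in% c("poppk_palivizumab", "poppk_bevacizumab")) {
      dn <- sub("poppk_", "", model_kind)
      cov <- covariate_set(bw, page_weeks = page_weeks(asp), sex = sex,
                           age_y = a)
      prof <- simulate_poppk(dn, cov, dose_regimen(dose_per_kg), times,
                             growth = growth)
      res <- nca_parameters(prof)
    } else {
      x <- if (model_kind == "allometric_0.75") 0.75 else 1
      res <- list(cl = cl_anchor * w70^x, vss = vss_anchor * w70,
                  t_half = NA_real_, auc_inf = dose_per_kg * bw * 1000 /
                    (cl_anchor * w70^x), extrapolated_fraction = 0)
    }
    data.frame(age_y = a, bw_kg = bw, dose_mg_kg = dose_per_kg,
               growth = growth, model_tag = model_kind,
               drug = drug$name,
               cl_ml_day = res$cl, cl_per_bw = res$cl / bw,
               cl_wtadj = res$cl / w70^0.75,
               vss_ml = res$vss, vss_per_bw = res$vss / bw,
               t_half_days = res$t_half,
               auc_inf = res$auc_inf,
               extrap_pct = res$extrapolated_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, adult_age = adult_age,
            class = c("age_sweep", "data.frame"))
}

# endosomal volume fraction shared between sweep constructions; kept as a
# function so analyses and tests agree on the default
endosomal_frac_default <- function() 0.005

#' Relative-to-adult scaling table
#'
#' Divides each age's body-weight-normalized clearance and steady-state
#' volume by the adult value of the same model family.
#'
#' @param sweep An [age_sweep()] result (or a rbind of several).
#' @param adult_age Adult reference age (default: from the sweep attribute).
#' @return The sweep with `rel_cl_bw` and `rel_vss_bw` columns added.
#' @export
relative_to_adult <- function(sweep, adult_age = attr(sweep, "adult_age")) {
  stopifnot(is.data.frame(sweep))
  if (is.null(adult_age)) adult_age <- 35
  key <- interaction(sweep$model_tag, sweep$growth, drop = TRUE)
  out <- do.call(rbind, lapply(split(sweep, key), function(d) {
    ad <- d[d$age_y == adult_age, ]
    if (nrow(ad) != 1)
      stop("adult reference row missing (or duplicated) for model_tag ",
           d$model_tag[1])
    d$rel_cl_bw <- d$cl_per_bw / ad$cl_per_bw
    d$rel_vss_bw <- d$vss_per_bw / ad$vss_per_bw
    d
  }))
  rownames(out) <- NULL
  structure(out, adult_age = adult_age, class = c("age_sweep", "data.frame"))
}

#' Effective allometric exponent of clearance
#'
#' Ordinary least squares of `log(CL)` on `log(BW)` across the sweep; the
#' slope is the effective exponent.
#'
#' @param sweep An [age_sweep()] result (single model family).
#' @return An object of class `allometric_fit` with `exponent`, `intercept`,
#'   `r2`, `n` and the body-weight range used.
#' @export
fit_allometric_exponent <- function(sweep) {
  stopifnot(is.data.frame(sweep), nrow(sweep) >= 4)
  bw <- sweep$bw_kg; cl <- sweep$cl_ml_day
  if (max(bw) / min(bw) < 5)
    stop("degenerate body-weight range: need at least 5-fold span")
  fit <- stats::lm(log(cl) ~ log(bw))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log(cl) - mean(log(cl)))^2)
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = if (tss > 0) 1 - rss / tss else 1,
                 n = nrow(sweep),
                 bw_range = range(bw),
                 age_range = range(sweep$age_y),
                 model_tag = sweep$model_tag[1],
                 growth = sweep$growth[1]),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf("<allometric_fit> %s (growth %s): CL ~ BW^%.3f (R2 %.4f, n %d, BW %.3g-%.3g kg)\n",
              x$model_tag, if (isTRUE(x$growth)) "on" else "off",
              x$exponent, x$r2, x$n, x$bw_range[1], x$bw_range[2]))
  invisible(x)
}

#' Join several sweeps into a comparison table
#'
#' Builds the long-format comparison of relative-to-adult CL/BW and Vss/BW
#' curves across model families, fits the effective allometric exponent per
#' family, and, where the same family appears with growth both on and off,
#' tabulates the growth-on/growth-off apparent-clearance ratio per age.
#'
#' @param sweeps A list of [age_sweep()] results sharing one age grid.
#' @return An object of class `model_comparison`: list with `table`
#'   (long-format relative curves), `exponents` (one `allometric_fit` per
#'   sweep) and `growth_cl_ratio`.
#' @export
compare_models <- function(sweeps) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1)
  grids <- lapply(sweeps, function(s) sort(unique(s$age_y)))
  if (!all(vapply(grids, identical, TRUE, y = grids[[1]])))
    stop("all sweeps must share the same age grid")
  rel <- do.call(rbind, lapply(sweeps, relative_to_adult))
  rownames(rel) <- NULL
  # exponent fits need >= 4 ages spanning a 5-fold weight range; smaller
  # sweeps are still comparable, just without a fit
  expos <- Filter(Negate(is.null), lapply(sweeps, function(s)
    tryCatch(fit_allometric_exponent(s), error = function(e) NULL)))
  tags <- unique(rel$model_tag)
  ratio <- NULL
  for (tg in tags) {
    on <- rel[rel$model_tag == tg & rel$growth, ]
    off <- rel[rel$model_tag == tg & !rel$growth, ]
    if (nrow(on) && nrow(off)) {
      mm <- merge(off[, c("age_y", "cl_ml_day")],
                  on[, c("age_y", "cl_ml_day")], by = "age_y",
                  suffixes = c("_off", "_on"))
      ratio <- rbind(ratio, data.frame(model_tag = tg, age_y = mm$age_y,
                                       cl_ratio = mm$cl_ml_day_on /
                                         mm$cl_ml_day_off))
    }
  }
  structure(list(table = rel, exponents = expos, growth_cl_ratio = ratio),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d rows, %d model families\n",
              nrow(x$table), length(unique(x$table$model_tag))))
  for (e in x$exponents) print(e)
  if (!is.null(x$growth_cl_ratio)) {
    cat("  growth-on / growth-off apparent-CL ratio:\n")
    print(utils::head(x$growth_cl_ratio, 12))
  }
  invisible(x)
}

#' @export
plot.age_sweep <- function(x, y = c("rel_cl_bw", "rel_vss_bw", "cl_wtadj"),
                           ...) {
  y <- match.arg(y)
  if (!y %in% names(x)) x <- relative_to_adult(x)
  tags <- unique(x$model_tag)
  cols <- seq_along(tags)
  graphics::plot(NULL, xlim = range(x$age_y), ylim = range(x[[y]], na.rm = TRUE),
                 xlab = "age [years]", ylab = y, ...)
  for (i in seq_along(tags)) {
    d <- x[x$model_tag == tags[i], ]
    graphics::lines(d$age_y, d[[y]], col = cols[i], type = "b", pch = 16)
  }
  graphics::legend("topright", legend = tags, col = cols, lty = 1, bty = "n")
  invisible(x)
}
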