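p_bev <- tmdd_parameters(kd_target = 0.058, koff = 3.1e-5, ksyn = 0.401,
                         kdeg_complex = 0.0482, r0 = 0.0113)

test_that("the drug-free steady state is stationary", {
  r <- tmdd_rates(c(D = 0, R = p_bev$r0, C = 0), p_bev)
  expect_equal(unname(r), c(0, 0, 0))
})

test_that("target turnover identity dR + dC = ksyn (R0 - R) - kdeg C holds", {
  set.seed(3)
  for (i in 1:20) {
    s <- c(D = runif(1, 0, 2), R = runif(1, 0, 0.02), C = runif(1, 0, 0.1))
    r <- tmdd_rates(s, p_bev)
    # the binding fluxes (~1e3/day) cancel exactly in dR + dC; allow only
    # floating-point cancellation error relative to their magnitude
    expect_equal(unname(r["dR"] + r["dC"]),
                 p_bev$ksyn * (p_bev$r0 - s[["R"]]) -
                   p_bev$kdeg_complex * s[["C"]],
                 tolerance = 1e-8)
  }
})

test_that("the association rate derives from koff/KD with exact consistency", {
  # independent unit path: koff [1/s] / KD [M], then to 1/(uM day)
  kon_M_s <- 3.1e-5 / (0.058 * 1e-9)          # 5.34e5 1/(M s)
  expect_equal(kon_M_s, 5.345e5, tolerance = 1e-3)
  expect_equal(p_bev$kon, kon_M_s * 86400 * 1e-6, tolerance = 1e-12)
  expect_equal(p_bev$kon * p_bev$kd_target / 1000, p_bev$koff_day,
               tolerance = 1e-12)
})

test_that("attachment is guarded and r0 = 0 reproduces the unattached model", {
  d <- bevacizumab_drug()
  m <- pbpk_model(make_growth_trajectory(age_spec(35)), d)
  mt <- attach_tmdd(m)
  expect_error(attach_tmdd(mt), "already")
  expect_identical(attach_tmdd(m, p = NULL)$tmdd, NULL)
  m0 <- attach_tmdd(m, tmdd_parameters(0.058, 3.1e-5, 0.401, 0.0482, r0 = 0))
  t <- nca_times(30, 1)
  expect_equal(simulate_pbpk(m0, dose_regimen(1), t)$conc_ug_ml,
               simulate_pbpk(m, dose_regimen(1), t)$conc_ug_ml,
               tolerance = 1e-8)
})

test_that("without dosing the attached target block stays at its steady state", {
  m <- attach_tmdd(pbpk_model(make_growth_trajectory(age_spec(35)),
                              bevacizumab_drug()))
  prof <- simulate_pbpk(m, dose_regimen(1e-15), seq(0, 50, 10))
  st <- attr(prof, "state")
  nx <- 2 * 9 + 2
  R <- st[, 29 + seq_len(nx)]
  C <- st[, 29 + nx + seq_len(nx)]
  expect_equal(max(abs(R - 1.5e-4)), 0, tolerance = 1e-10)
  expect_lt(max(abs(C)), 1e-12)
})

test_that("target binding is negligible at therapeutic doses but pronounced below", {
  aucs <- bev_auc_by_dose()
  dn <- aucs$tmdd / c(0.1, 5, 10, 15)     # dose-normalized AUCs
  lin <- aucs$lin1                        # linear reference (1 mg/kg, no TMDD)
  expect_lt(abs(dn[2] - lin) / lin, 0.05)
  expect_lt(abs(dn[3] - lin) / lin, 0.05)
  expect_lt(abs(dn[4] - lin) / lin, 0.05)
  expect_lt(dn[1], 0.75 * lin)            # strong TMDD at 0.1 mg/kg
  expect_true(all(diff(dn) > 0))          # dose-normalized AUC rises with dose
})

test_that("r0 is practically unidentifiable from a single therapeutic dose group", {
  d <- bevacizumab_drug()
  # within the sampling month of a therapeutic dose the target is saturated;
  # the distinguishing signal appears only during late washout
  sim <- function(r0, dose) {
    dd <- bevacizumab_drug(tmdd = tmdd_parameters(0.058, 3.1e-5, 0.401,
                                                  0.0482, r0))
    m <- attach_tmdd(pbpk_model(make_growth_trajectory(age_spec(35)), dd))
    simulate_pbpk(m, dose_regimen(dose), nca_times(28, 1))$conc_ug_ml
  }
  rel_change <- function(dose) {
    a <- sim(1.5e-4, dose); b <- sim(1.5e-3, dose)
    max(abs(b - a) / pmax(a, 1e-9))
  }
  expect_lt(rel_change(10), 0.10)   # 10x r0 barely moves the therapeutic curve
  expect_gt(rel_change(0.1), 0.50)  # but transforms the sub-therapeutic one
})

test_that("zero-noise synthetic data are recovered essentially exactly", {
  truth <- bevacizumab_drug()
  des <- study_design("zero-noise recovery", "bevacizumab",
                      dose_groups = c(0.1, 1, 10), n_per_group = c(1, 1, 1),
                      age_mean_y = 35, age_sd_y = 0, age_range_y = c(35, 35),
                      sampling_days = c(0.25, 1, 2, 7, 14, 21, 30, 50, 70),
                      population = "adult")
  obs <- generate_observed(des, pbpk_simulator(truth), noise_model(0, 0, seed = 1))
  tmpl <- pbpk_model(make_growth_trajectory(age_spec(35)),
                     bevacizumab_drug(tmdd = NULL))
  tmpl$drug$tmdd <- truth$tmdd
  fit <- fit_tmdd_and_fcrn(obs, tmpl,
                           start = c(kd_fcrn = 0.5, r0 = 3e-4,
                                     kdeg_complex = 0.1))
  truth_par <- c(kd_fcrn = 0.884, r0 = 1.5e-4, kdeg_complex = 0.0482)
  expect_equal(coef(fit), truth_par, tolerance = 0.01)
  expect_lt(fit$residual_sd, 1e-3)
})
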