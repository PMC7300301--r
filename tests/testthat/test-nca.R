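# closed-form mono-exponential fixtures
mono_profile <- function(c0, k, t) pk_profile(t, c0 * exp(-k * t))

test_that("AUC matches mono-exponential closed forms", {
  t <- seq(0, 70, by = 0.05)
  p <- mono_profile(100, 0.1, t)
  expect_equal(nca_auc(p), 100 / 0.1 * (1 - exp(-7)), tolerance = 1e-6)
  expect_equal(nca_auc(p), 999.1, tolerance = 1e-4)
  # an all-zero profile has zero area
  z <- pk_profile(t, rep(0, length(t)))
  expect_equal(nca_auc(z), 0)
})

test_that("AUC is additive over windows and monotone in concentrations", {
  t <- seq(0, 50, by = 0.25)
  p <- mono_profile(80, 0.07, t)
  expect_equal(nca_auc(p, 0, 20) + nca_auc(p, 20, 50), nca_auc(p, 0, 50),
               tolerance = 1e-12)
  p2 <- pk_profile(t, 1.2 * p$conc_ug_ml)
  expect_gt(nca_auc(p2), nca_auc(p))
  expect_error(nca_auc(p, -1, 20), "outside")
  expect_error(nca_auc(p, 0, 60), "outside")
})

test_that("linear and lin-log methods agree on densely sampled smooth decays", {
  t <- seq(0, 70, by = 0.1)
  p <- mono_profile(120, 0.05, t)
  expect_equal(nca_auc(p, method = "linear"), nca_auc(p, method = "linlog"),
               tolerance = 0.005)
})

test_that("terminal phase recovers a pure exponential rate exactly", {
  t <- seq(0, 100, by = 1)
  p <- mono_profile(50, 0.035, t)
  term <- terminal_phase(p)
  expect_equal(term$lambda_z, 0.035, tolerance = 1e-10)
  expect_equal(term$t_half, log(2) / 0.035, tolerance = 1e-10)
  expect_gte(term$n_points, 3)
  # too few points for a window is a quality error
  expect_error(terminal_phase(mono_profile(50, 0.035, c(0, 1, 2))), "terminal")
})

test_that("one-compartment NCA recovers CL and Vss within 0.5%", {
  cl <- 150; v <- 5000; dose_mg <- 500
  k <- cl / v
  t <- seq(0, 8 / k, by = 0.05 / k)
  p <- mono_profile(dose_mg * 1000 / v, k, t)
  n <- nca_parameters(p, dose_mg = dose_mg)
  expect_equal(n$cl, cl, tolerance = 0.005)
  expect_equal(n$vss, v, tolerance = 0.005)
  expect_equal(n$mrt, 1 / k, tolerance = 0.005)
})

test_that("dense popPK palivizumab profile satisfies dose/CL and Vc+Vp identities", {
  p <- palivizumab_parameters(covariate_set(70, page_weeks = Inf))
  attr(p, "bw") <- 70
  prof <- simulate_two_compartment(p, dose_regimen(15), seq(0, 250, by = 0.1))
  n <- nca_parameters(prof, dose_mg = 15 * 70)
  expect_equal(n$auc_inf, 15 * 70 * 1000 / 198, tolerance = 0.01)
  expect_equal(n$auc_inf, 5303, tolerance = 0.011)
  expect_equal(n$vss, 6320, tolerance = 0.02)
})

test_that("extrapolation beyond 20% is flagged", {
  t <- seq(0, 15, by = 0.25)               # short window, long half-life
  p <- mono_profile(100, 0.02, t)
  n <- nca_parameters(p, dose_mg = 1)
  expect_gt(n$extrapolated_fraction, 20)
  expect_true(n$extrapolation_flag)
})
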