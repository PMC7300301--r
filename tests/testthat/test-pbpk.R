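test_that("drug is conserved when all clearance terms are off", {
  d <- palivizumab_drug()
  m <- pbpk_model(make_growth_trajectory(age_spec(35)), d,
                  endosomal = endosomal_parameters(clearance_rate = 0))
  prof <- simulate_pbpk(m, dose_regimen(10), seq(0, 100, by = 5))
  st <- attr(prof, "state")
  total <- rowSums(st)
  expect_equal(max(abs(total - total[1]) / total[1]), 0, tolerance = 1e-6)
})

test_that("without TMDD the system is linear in dose", {
  d <- pali_calibrated()
  m <- pbpk_model(make_growth_trajectory(age_spec(5)), d)
  t <- nca_times(30, 1)
  p1 <- simulate_pbpk(m, dose_regimen(5), t)
  p2 <- simulate_pbpk(m, dose_regimen(10), t)
  expect_equal(p2$conc_ug_ml, 2 * p1$conc_ug_ml, tolerance = 1e-8)
})

test_that("state variables stay non-negative at solver output points", {
  d <- pali_calibrated()
  for (g in c(FALSE, TRUE)) {
    m <- pbpk_model(make_growth_trajectory(age_spec(0), g), d)
    prof <- simulate_pbpk(m, dose_regimen(15), nca_times(70, 1))
    st <- attr(prof, "state")
    expect_gte(min(st), -1e-8 * max(st))
  }
})

test_that("clearance increases with Kd(FcRn) and decreases with free FcRn", {
  base <- palivizumab_drug()
  cl_kd <- sapply(c(0.3, 0.8, 2), function(kd) {
    m <- pbpk_model(make_growth_trajectory(age_spec(35)),
                    palivizumab_drug(kd))
    adult_cl_of(m)
  })
  expect_true(all(diff(cl_kd) > 0))
  cl_fcrn <- sapply(c(1, 2), function(f) {
    m <- pbpk_model(make_growth_trajectory(age_spec(35)), base,
                    endosomal = endosomal_parameters(free_fcrn = f))
    adult_cl_of(m)
  })
  expect_lt(cl_fcrn[2], cl_fcrn[1])
})

test_that("FcRn calibration round-trips and is monotone", {
  d <- palivizumab_drug(0.8)
  m <- pbpk_model(make_growth_trajectory(age_spec(35)), d)
  target <- adult_cl_of(m, days = 150, dt = 0.5)
  kd <- calibrate_fcrn_kd(m, target)
  expect_equal(as.numeric(kd), 0.8, tolerance = 1e-3)
  expect_equal(attr(kd, "cl"), target, tolerance = 1e-3)
  # a larger clearance target needs a larger Kd
  kd2 <- calibrate_fcrn_kd(m, target * 1.3)
  expect_gt(as.numeric(kd2), as.numeric(kd))
  # unattainable targets report the attainable interval
  expect_error(calibrate_fcrn_kd(m, 1e9), "attainable")
})

test_that("NCA clearance is insensitive to the sampling grid and solver tolerance", {
  d <- pali_calibrated()
  m <- pbpk_model(make_growth_trajectory(age_spec(35)), d)
  n1 <- nca_parameters(simulate_pbpk(m, dose_regimen(10), nca_times(150, 0.5)))
  n2 <- nca_parameters(simulate_pbpk(m, dose_regimen(10), nca_times(150, 0.05)))
  expect_equal(n1$cl, n2$cl, tolerance = 0.01)
  a1 <- nca_parameters(simulate_pbpk(m, dose_regimen(10), nca_times(150, 0.5),
                                     rtol = 1e-8, atol = 1e-10))$auc_inf
  a2 <- nca_parameters(simulate_pbpk(m, dose_regimen(10), nca_times(150, 0.5),
                                     rtol = 5e-9, atol = 5e-11))$auc_inf
  expect_equal(a1, a2, tolerance = 1e-4)
})

test_that("a zero-concentration profile results from no dosing input", {
  d <- palivizumab_drug()
  m <- pbpk_model(make_growth_trajectory(age_spec(35)), d)
  reg <- dose_regimen(1e-12)   # vanishing dose stands in for no dose
  prof <- simulate_pbpk(m, reg, seq(0, 10, 1))
  expect_lt(max(prof$conc_ug_ml), 1e-9)
})

test_that("infusion and bolus administrations deliver the same amount", {
  d <- pali_calibrated()
  m <- pbpk_model(make_growth_trajectory(age_spec(35)), d)
  t <- nca_times(100, 0.5)
  nb <- nca_parameters(simulate_pbpk(m, dose_regimen(10), t))
  ni <- nca_parameters(simulate_pbpk(m, dose_regimen(10, duration = 0.05), t))
  expect_equal(ni$auc_inf, nb$auc_inf, tolerance = 0.005)
})

test_that("growth flag is a no-op for an adult", {
  d <- pali_calibrated()
  t <- nca_times(30, 1)
  p0 <- simulate_pbpk(pbpk_model(make_growth_trajectory(age_spec(35), FALSE), d),
                      dose_regimen(10), t)
  p1 <- simulate_pbpk(pbpk_model(make_growth_trajectory(age_spec(35), TRUE), d),
                      dose_regimen(10), t)
  expect_equal(p1$conc_ug_ml, p0$conc_ug_ml, tolerance = 1e-6)
})
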