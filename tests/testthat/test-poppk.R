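test_that("palivizumab parameters reproduce the published worked values", {
  ad <- palivizumab_parameters(covariate_set(70, page_weeks = Inf))
  expect_equal(ad$cl, 198)
  expect_equal(ad$vc, 4090)
  expect_equal(ad$vp, 2230)
  expect_equal(ad$q, 879)
  expect_equal(ad$cl / 70, 2.83, tolerance = 0.002)
  # maturation at its anchor multiplies clearance by 0.411
  anchored <- palivizumab_parameters(covariate_set(70, page_weeks = 404.35))
  expect_equal(anchored$cl, 198 * 0.411, tolerance = 1e-10)
  # pure allometry at 70/8 kg
  small <- palivizumab_parameters(covariate_set(8.75, page_weeks = Inf))
  expect_equal(small$cl, 198 * 8^-0.75, tolerance = 1e-10)
  expect_equal(small$cl, 41.63, tolerance = 1e-3)
})

test_that("bevacizumab parameters apply the printed covariate factors", {
  f <- bevacizumab_parameters(covariate_set(70, sex = "female"))
  expect_equal(f$cl, 237.6)
  expect_equal(f$vc, 2850)
  expect_equal(f$vp, 2564)
  expect_equal(f$q, 672)
  m_cns <- bevacizumab_parameters(covariate_set(70, sex = "male",
                                                cns_tumor = TRUE))
  expect_equal(m_cns$cl, 237.6 * 1.11 * 0.725, tolerance = 1e-10)
  expect_equal(m_cns$cl, 191.2, tolerance = 1e-3)
  m <- bevacizumab_parameters(covariate_set(70, sex = "male"))
  expect_equal(m$vc, 2850 * 1.14)
})

test_that("the maturation factor is clamped, bounded and non-decreasing", {
  pg <- seq(30, 3000, by = 10)
  m <- maturation_factor(pg)
  expect_true(all(m >= 0.411 & m <= 1))
  expect_true(all(diff(m) >= 0))
  expect_equal(maturation_factor(40), 0.411)       # newborn: clamped
  expect_equal(maturation_factor(1e5), 1)
  # the literal formula below the anchor would fall under the plateau
  expect_lt(maturation_factor(100, clamp = FALSE), 0.411)
})

test_that("closed-form and ODE solutions agree to 0.01%", {
  p <- palivizumab_parameters(covariate_set(70, page_weeks = Inf))
  attr(p, "bw") <- 70
  reg <- dose_regimen(15)
  t <- seq(0.25, 70, by = 0.25)
  closed <- simulate_two_compartment(p, reg, t)
  ode <- simulate_two_compartment(function(tt) p, reg, t, growth = TRUE,
                                  bw_fn = function(tt) 70)
  expect_lt(max(abs(ode$conc_ug_ml - closed$conc_ug_ml) / closed$conc_ug_ml),
            1e-4)
})

test_that("bolus initial condition is dose/Vc and the beta half-life matches its eigenvalue", {
  p <- palivizumab_parameters(covariate_set(70, page_weeks = Inf))
  attr(p, "bw") <- 70
  prof <- simulate_two_compartment(p, dose_regimen(15), c(0, 1, 2))
  expect_equal(prof$conc_ug_ml[1], 15 * 70 * 1000 / 4090, tolerance = 1e-10)
  # independent eigenvalue oracle for the slow rate constant
  A <- matrix(c(-(198 + 879) / 4090, 879 / 2230,
                879 / 4090, -879 / 2230), 2, 2, byrow = TRUE)
  beta <- -max(eigen(A)$values)
  expect_equal(two_compartment_beta_half_life(p), log(2) / beta,
               tolerance = 1e-10)
  expect_equal(two_compartment_beta_half_life(p), 22.78, tolerance = 1e-3)
})

test_that("Vss equals Vc + Vp and dense-profile NCA recovers it within 2%", {
  p <- palivizumab_parameters(covariate_set(70, page_weeks = Inf))
  attr(p, "bw") <- 70
  prof <- simulate_two_compartment(p, dose_regimen(15), seq(0, 250, by = 0.1))
  n <- nca_parameters(prof, dose_mg = 15 * 70)
  expect_equal(n$vss, 4090 + 2230, tolerance = 0.02)
  expect_equal(n$cl, 198, tolerance = 0.01)
  expect_equal(n$t_half, two_compartment_beta_half_life(p), tolerance = 0.02)
})

test_that("growth during simulation raises the apparent clearance of an infant", {
  asp <- age_spec(0.25)
  bw <- build_reference_physiology(asp)$body_weight
  cov <- covariate_set(bw, page_weeks = page_weeks(asp), age_y = 0.25)
  t <- seq(0, 70, by = 0.25)
  off <- simulate_poppk("palivizumab", cov, dose_regimen(15), t, growth = FALSE)
  on <- simulate_poppk("palivizumab", cov, dose_regimen(15), t, growth = TRUE)
  cl_off <- nca_parameters(off)$cl
  cl_on <- nca_parameters(on)$cl
  expect_gt(cl_on, cl_off)
  # an adult is unaffected by the growth flag
  cov_ad <- covariate_set(70, page_weeks = Inf, age_y = 35)
  a_off <- simulate_poppk("palivizumab", cov_ad, dose_regimen(15), t, FALSE)
  a_on <- simulate_poppk("palivizumab", cov_ad, dose_regimen(15), t, TRUE)
  expect_equal(a_on$conc_ug_ml, a_off$conc_ug_ml, tolerance = 1e-6)
})
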