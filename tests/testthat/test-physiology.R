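test_that("reference anthropometry matches published reference individuals", {
  ad <- build_reference_physiology(age_spec(35))
  expect_gt(ad$body_weight, 65)
  expect_lt(ad$body_weight, 75)
  nb <- build_reference_physiology(age_spec(0))
  expect_gte(nb$body_weight, 3.2)
  expect_lte(nb$body_weight, 3.6)
  # interpolation reproduces table nodes exactly
  expect_equal(build_reference_physiology(age_spec(5))$body_weight, 19)
  expect_equal(build_reference_physiology(age_spec(1, sex = "female"))$body_weight,
               9.2)
})

test_that("snapshots are strictly positive and flow-consistent at all ages", {
  for (a in c(0, 0.1, 0.25, 0.7, 1, 3, 5, 12, 35, 60, 80)) {
    s <- build_reference_physiology(age_spec(a))
    o <- s$organs
    expect_true(all(unlist(o[-1]) > 0), label = sprintf("positivity age %g", a))
    # lymph flow is an age-independent organ-specific fraction of plasma flow
    tab <- read.csv(system.file("extdata", "organs.csv", package = "pedmabpk"))
    expect_equal(o$lymph_flow / o$plasma_flow,
                 tab$lymph_frac_flow[match(o$organ, tab$organ)],
                 tolerance = 1e-12)
    # endosomal/vascular ratio constant across organs and ages
    expect_equal(o$endosomal_volume / o$plasma_volume, rep(0.005, nrow(o)),
                 tolerance = 1e-12)
    # systemic organ plasma flows sum to at most the cardiac plasma output
    expect_lte(sum(o$plasma_flow[o$organ != "lung"]),
               s$cardiac_output_plasma * (1 + 1e-12))
  }
})

test_that("body-weight-normalized plasma volume is higher in the newborn than the adult", {
  tot_pl <- function(a) {
    s <- build_reference_physiology(age_spec(a))
    (sum(s$organs$plasma_volume) + s$venous_plasma + s$arterial_plasma) /
      s$body_weight
  }
  expect_gt(tot_pl(0), tot_pl(35))
  expect_gt(tot_pl(0.5), tot_pl(35))
})

test_that("age validation and table range errors are raised", {
  expect_error(age_spec(-1))
  expect_error(age_spec(1, gestational_age = 20), "gestational")
  expect_error(build_reference_physiology(age_spec(95)), "outside")
})

test_that("PAGE bookkeeping converts between weeks and months consistently", {
  a <- age_spec(0)
  expect_equal(page_weeks(a), 40)
  expect_equal(page_months(a), 40 * 7 / (365.25 / 12))
  expect_equal(page_weeks(a, at_days = 365.25), 40 + 365.25 / 7 * 1)
})

test_that("growth-disabled trajectories are constant; growth-enabled ones grow", {
  tr0 <- make_growth_trajectory(age_spec(0), FALSE)
  s0 <- tr0$snapshot(0)
  expect_identical(tr0$snapshot(60), s0)
  expect_identical(tr0$snapshot(300), s0)
  tr1 <- make_growth_trajectory(age_spec(0), TRUE)
  bw <- sapply(seq(0, 600, by = 30), function(t) tr1$snapshot(t)$body_weight)
  expect_true(all(diff(bw) > 0))
  expect_gt(tr1$snapshot(60)$body_weight, s0$body_weight)
  # snapshot(t) equals a direct table lookup at age + t
  direct <- build_reference_physiology(age_spec(0 + 90 / 365.25))
  expect_equal(tr1$snapshot(90)$organs, direct$organs, tolerance = 1e-12)
})

test_that("weight override rescales mass-proportional quantities", {
  s <- build_reference_physiology(age_spec(0.5), weight_override = 5.5)
  ref <- build_reference_physiology(age_spec(0.5))
  f <- 5.5 / ref$body_weight
  expect_equal(s$body_weight, 5.5)
  expect_equal(s$organs$plasma_volume, ref$organs$plasma_volume * f)
  expect_equal(s$body_height, ref$body_height)
})

test_that("population-PK body-weight rules reproduce the printed piecewise rates", {
  expect_equal(poppk_bodyweight_update(10, 12, 7.00), 8.78)
  expect_equal(poppk_bodyweight_update(14, 16, 9.00), 9.48)
  expect_equal(poppk_bodyweight_update(12, 14, 8.00), 9.13)
  expect_error(poppk_bodyweight_update(14, 12, 8), "page_now")
})

test_that("body-weight update composes over intermediate PAGE points", {
  set.seed(11)
  for (i in 1:25) {
    p <- sort(runif(3, 5, 20))
    direct <- poppk_bodyweight_update(p[1], p[3], 6)
    via <- poppk_bodyweight_update(p[2], p[3],
                                   poppk_bodyweight_update(p[1], p[2], 6))
    expect_equal(via, direct, tolerance = 1e-12)
  }
})
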