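# Shared fixtures: expensive calibrations and sweeps computed once per test
# run and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, expr, envir = .fixture_cache)
  .fixture_cache[[key]]
}

# NCA clearance of a model after a single 10 mg/kg dose
adult_cl_of <- function(m, days = 100, dt = 1) {
  prof <- simulate_pbpk(m, dose_regimen(10), nca_times(days, dt))
  nca_parameters(prof)$cl
}

adult_pbpk <- function(drug, tmdd = !is.null(drug$tmdd)) {
  m <- pbpk_model(make_growth_trajectory(age_spec(35)), drug)
  if (tmdd) m <- attach_tmdd(m)
  m
}

# palivizumab calibrated so the simulated adult NCA clearance is 198 ml/day
pali_calibrated <- function() {
  cached("pali_drug", {
    d <- palivizumab_drug()
    d$kd_fcrn <- as.numeric(calibrate_fcrn_kd(adult_pbpk(d), 198))
    d
  })
}

# bevacizumab (with TMDD) calibrated to the adult popPK clearance
bev_calibrated <- function() {
  cached("bev_drug", {
    d <- bevacizumab_drug()
    d$kd_fcrn <- as.numeric(calibrate_fcrn_kd(adult_pbpk(d), 237.6))
    d
  })
}

# default-grid palivizumab PBPK sweeps (10 mg/kg), growth off / on
sweep_pali <- function(growth) {
  cached(paste0("sweep_pali_", growth),
         age_sweep(pali_calibrated(), "pbpk", dose_per_kg = 10,
                   growth = growth))
}

# newborn 15 mg/kg, 70-day pair for the growth-effect readout
newborn_growth_pair <- function() {
  cached("newborn_pair", {
    d <- pali_calibrated()
    sim <- function(g) {
      m <- pbpk_model(make_growth_trajectory(age_spec(0), g), d)
      nca_parameters(simulate_pbpk(m, dose_regimen(15), nca_times(70, 0.25)))
    }
    list(off = sim(FALSE), on = sim(TRUE))
  })
}

# adult bevacizumab AUCs with and without target binding at several doses
bev_auc_by_dose <- function() {
  cached("bev_aucs", {
    d <- bevacizumab_drug()
    m0 <- adult_pbpk(d, tmdd = FALSE)
    mt <- adult_pbpk(d, tmdd = TRUE)
    one <- function(m, dose)
      nca_parameters(simulate_pbpk(m, dose_regimen(dose),
                                   nca_times(150, 0.5)))$auc_inf
    list(lin1 = one(m0, 1),
         tmdd = sapply(c(0.1, 5, 10, 15), function(dd) one(mt, dd)))
  })
}
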