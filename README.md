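# pedmabpk

Whole-body PBPK and population-PK scaling of therapeutic IgG antibodies
from adults to children.

## What problem this package addresses

Monoclonal IgG antibodies are cleared by endosomal catabolism with FcRn
protection and distributed by slow, pore-limited extravasation — processes
whose maturation from birth to adulthood is poorly characterized.  Pediatric
dosing therefore rests on scaling assumptions.  `pedmabpk` is for
pharmacometricians and modelers who want to ask, with fully auditable
machinery: *assuming no antibody-specific ontogeny at all* — only the
documented growth of anatomy, flows and body composition — what pediatric PK
does a mechanistic whole-body model predict, and how does that compare with
published population-PK models and with plain allometric scaling?

The package implements:

* a reduced **whole-body PBPK model** for IgG (9 lumped organs + plasma
  pools): two-pore transcapillary exchange (small pores 4.44 nm, large
  22.85 nm, Patlak convection–diffusion flux with
  `Pe = J_v(1-σ)/PS`), lymph and recirculation return, and endosomal uptake
  with instantaneous FcRn partition — the unbound fraction
  `f_u = K_d/(K_d + [FcRn])` is degraded, the bound fraction recycled;
* **age- and sex-resolved reference physiology** (embedded, documented CSV
  tables; term newborn to 80 y) with optional continuous **growth during
  simulation**;
* the paper-trail calibration step: `calibrate_fcrn_kd()` root-finds
  `K_d(FcRn)` so the simulated adult NCA clearance matches an observed adult
  clearance (e.g. palivizumab 198 ml/day = 2.83 ml/day/kg);
* an optional full (non-quasi-steady-state) **TMDD** extension
  (`dD/dt = -k_on·D·R + k_off·C`, etc., with `k_on = k_off/K_D`) and a
  pooled multi-dose-group fit `fit_tmdd_and_fcrn()`;
* the printed **2-compartment population-PK comparators** for palivizumab
  (allometry × maturation on PAGE, piecewise body-weight growth rules) and
  bevacizumab (allometry + sex/CNS covariates);
* **NCA** (lin-up/log-down AUC, automatic terminal window, CL, Vss, MRT) and
  the **scaling pipeline**: age sweeps, relative-to-adult curves, and
  effective allometric exponents from OLS of log CL on log BW;
* a seeded **synthetic study generator** emulating the five source clinical
  designs, so every pipeline stage is testable without any external data.

## Worked example

Calibrate the adult palivizumab model to the adult population-PK clearance,
then predict a growing 6-month-old infant given 15 mg/kg IV:

```r
library(pedmabpk)

pali  <- palivizumab_drug()
adult <- pbpk_model(make_growth_trajectory(age_spec(35)), pali)
kd    <- calibrate_fcrn_kd(adult, target_cl = 198)   # ml/day
pali$kd_fcrn <- as.numeric(kd)                       # 0.7348 uM (CL 198.0)

infant <- pbpk_model(make_growth_trajectory(age_spec(0.5), growth_enabled = TRUE),
                     pali)
prof <- simulate_pbpk(infant, dose_regimen(15), nca_times(70, 0.25))
prof
#> <pk_profile> 292 points over 70 d; palivizumab 15 mg/kg, age 0.5 y, growth on
#>   Cmax 1.66e+03 ug/ml, Clast 15.1 ug/ml
nca_parameters(prof)
#> <nca_result>
#>   AUC_0-t 3755, AUC_inf 4268 ug day/ml (extrapolated 12.0%)
#>   lambda_z 0.02942 1/day (T1/2 23.6 d, window 69.5-70 d, n=3, adj-R2 1.00000)
#>   CL 27.76 ml/day, Vss 893.4 ml, MRT 32.2 d
```

Reading the output: the calibrated FcRn affinity (0.73 µM) lands near the
experimentally reported ~0.75 µM without being fitted to it.  The 7.9-kg
infant's apparent clearance, 27.8 ml/day (3.5 ml/day/kg), is moderately
above the adult's on a per-kg basis (2.83 ml/day/kg), and the 23.6-day
half-life sits inside the published 17–26.8-day range for palivizumab.  The
early Cmax is the venous-pool value immediately after the bolus; mixing
settles within minutes (hence the log-spaced early samples from
`nca_times()`).

The scaling analysis condenses such simulations across ages:

```r
sweep <- age_sweep(pali, "pbpk", dose_per_kg = 10, growth = FALSE)
fit_allometric_exponent(sweep)
#> <allometric_fit> pbpk (growth off): CL ~ BW^0.954 (R2 0.9965, n 9, BW 3.5-73 kg)
```

i.e. the mechanistic model's clearance scales with an effective exponent
between the bevacizumab popPK description (0.75) and the palivizumab one
(effectively ~1) — the package's central reproduction.

Configuration-file entry points (`cmd_simulate()`, `cmd_sweep_compare()`,
YAML/JSON schema in `?read_run_config`, example under `inst/examples/`)
write tidy CSV/JSON stamped with a config hash; a thin command-line wrapper
is provided in `inst/scripts/pedmabpk-cli.R`.

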