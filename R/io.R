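# Configuration-driven entry points: one-shot simulation + NCA, and the
# multi-model age-sweep comparison.  Configs are YAML or JSON; every output
# carries the config hash and package version for provenance.

.config_keys <- list(
  top = c("drug", "individual", "regimen", "analysis", "output_dir", "seed"),
  drug = c("name", "kd_fcrn", "molecular_weight", "hydrodynamic_radius",
           "tmdd", "calibrate_to"),
  tmdd = c("kd_target", "koff", "ksyn", "kdeg_complex", "r0"),
  individual = c("age_y", "sex", "gestational_age_weeks", "weight_override",
                 "cns_tumor"),
  regimen = c("dose_mg_kg", "time", "duration"),
  analysis = c("model_kind", "growth", "obs_days", "dt", "ages", "adult_age"))

.check_keys <- function(block, allowed, path) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown configuration key(s) at %s: %s", path,
                 paste(bad, collapse = ", ")))
}

#' Read and validate a run configuration
#'
#' @param path A YAML (`.yml`/`.yaml`) or JSON (`.json`) file, or an
#'   already-parsed list.
#' @return A validated list of class `run_config`; unknown keys anywhere in
#'   the document are rejected.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file, or a list")
  if (!is.list(cfg)) stop("malformed configuration: not a mapping")
  .check_keys(cfg, .config_keys$top, "top level")
  for (blk in c("drug", "individual", "regimen", "analysis"))
    if (!is.null(cfg[[blk]])) .check_keys(cfg[[blk]], .config_keys[[blk]], blk)
  if (!is.null(cfg$drug$tmdd)) .check_keys(cfg$drug$tmdd, .config_keys$tmdd,
                                           "drug$tmdd")
  if (is.null(cfg$regimen$dose_mg_kg)) stop("regimen$dose_mg_kg is required")
  structure(cfg, class = c("run_config", "list"))
}

.config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

.cfg_drug <- function(cfg) {
  d <- cfg$drug
  name <- if (is.null(d$name)) "mab" else d$name
  tm <- if (!is.null(d$tmdd))
    tmdd_parameters(d$tmdd$kd_target, d$tmdd$koff, d$tmdd$ksyn,
                    d$tmdd$kdeg_complex, d$tmdd$r0)
  else if (identical(name, "bevacizumab")) bevacizumab_drug()$tmdd
  else NULL
  kd <- if (!is.null(d$kd_fcrn)) d$kd_fcrn
  else if (identical(name, "palivizumab")) 0.863
  else if (identical(name, "bevacizumab")) 0.884 else 1
  drug_properties(name,
                  molecular_weight = d$molecular_weight %||% 150,
                  hydrodynamic_radius = d$hydrodynamic_radius %||% 5.34,
                  kd_fcrn = kd, tmdd = tm)
}

.cfg_age <- function(cfg) {
  i <- cfg$individual
  age_spec(i$age_y %||% 35,
           gestational_age = i$gestational_age_weeks %||% 40,
           sex = i$sex %||% "male")
}

.provenance_header <- function(cfg) {
  c(sprintf("# pedmabpk %s", as.character(utils::packageVersion("pedmabpk"))),
    sprintf("# config_hash %s", .config_hash(cfg)))
}

# verbatim echo of the configuration next to the results
.echo_config <- function(cfg, out_dir) {
  p <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  p
}

.write_csv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run one simulation from a configuration
#'
#' Simulates the configured model (PBPK or population PK) for one
#' individual, writes the profile as tidy CSV and the NCA parameters as
#' JSON, both stamped with the configuration hash.  With
#' `drug$calibrate_to` set (ml/day), the FcRn affinity is calibrated at
#' adult physiology before simulation.
#'
#' @param config Path to a YAML/JSON config, or a list (see
#'   [read_run_config()]).
#' @param output_dir Overrides the config's `output_dir` (default: temp
#'   directory).
#' @return Invisibly, a list with `profile`, `nca` and the output `paths`.
#' @export
cmd_simulate <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||% tempfile("pedmabpk_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  an <- cfg$analysis %||% list()
  kind <- an$model_kind %||% "pbpk"
  growth <- isTRUE(an$growth)
  obs_days <- an$obs_days %||% 70
  times <- nca_times(obs_days, an$dt %||% 0.25)
  reg <- dose_regimen(cfg$regimen$dose_mg_kg,
                      time = cfg$regimen$time %||% 0,
                      duration = cfg$regimen$duration %||% 0)
  asp <- .cfg_age(cfg)
  if (kind == "pbpk") {
    drug <- .cfg_drug(cfg)
    if (!is.null(cfg$drug$calibrate_to)) {
      adult <- pbpk_model(make_growth_trajectory(
        age_spec(35, sex = asp$sex)), drug)
      if (!is.null(drug$tmdd)) adult <- attach_tmdd(adult)
      drug$kd_fcrn <- as.numeric(calibrate_fcrn_kd(adult, cfg$drug$calibrate_to))
    }
    traj <- make_growth_trajectory(asp, growth_enabled = growth,
                                   weight_override = cfg$individual$weight_override)
    m <- pbpk_model(traj, drug)
    if (!is.null(drug$tmdd)) m <- attach_tmdd(m)
    prof <- simulate_pbpk(m, reg, times)
  } else if (kind %in% c("poppk_palivizumab", "poppk_bevacizumab")) {
    bw <- cfg$individual$weight_override %||%
      build_reference_physiology(asp)$body_weight
    cov <- covariate_set(bw, page_weeks = page_weeks(asp), sex = asp$sex,
                         cns_tumor = isTRUE(cfg$individual$cns_tumor),
                         age_y = asp$postnatal_age)
    prof <- simulate_poppk(sub("poppk_", "", kind), cov, reg, times,
                           growth = growth)
  } else stop("unknown analysis$model_kind: ", kind)
  nca <- nca_parameters(prof)
  hdr <- .provenance_header(cfg)
  p_csv <- file.path(out_dir, "profile.csv")
  df <- data.frame(time_days = prof$time_days, conc_ug_ml = prof$conc_ug_ml,
                   id = 1L, dose_mg_kg = cfg$regimen$dose_mg_kg[1],
                   growth_flag = growth)
  .write_csv_with_header(df, p_csv, hdr)
  p_json <- file.path(out_dir, "nca.json")
  jsonlite::write_json(c(list(package = hdr[1], config_hash = .config_hash(cfg)),
                         unclass(nca)[c("auc_0_t", "auc_inf", "lambda_z",
                                        "t_half", "cl", "vss", "mrt",
                                        "extrapolated_fraction")]),
                       p_json, auto_unbox = TRUE, digits = NA)
  p_cfg <- .echo_config(cfg, out_dir)
  invisible(list(profile = prof, nca = nca,
                 paths = c(profile = p_csv, nca = p_json, config = p_cfg)))
}

#' Run the multi-model age-sweep comparison from a configuration
#'
#' Runs [age_sweep()] for each configured model kind, derives
#' relative-to-adult curves and effective allometric exponents, and writes
#' the long-format comparison table (CSV) plus the exponent fits (JSON).
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the [compare_models()] result plus output `paths`.
#' @export
cmd_sweep_compare <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- output_dir %||% cfg$output_dir %||% tempfile("pedmabpk_sweep_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  an <- cfg$analysis %||% list()
  kinds <- an$model_kind %||% c("pbpk", "allometric_0.75")
  ages <- an$ages %||% .DEFAULT_AGES
  drug <- .cfg_drug(cfg)
  if (!is.null(cfg$drug$calibrate_to)) {
    adult <- pbpk_model(make_growth_trajectory(age_spec(35)), drug)
    if (!is.null(drug$tmdd)) adult <- attach_tmdd(adult)
    drug$kd_fcrn <- as.numeric(calibrate_fcrn_kd(adult, cfg$drug$calibrate_to))
  }
  sweeps <- lapply(kinds, function(k)
    age_sweep(drug, k, ages = ages,
              dose_per_kg = cfg$regimen$dose_mg_kg[1],
              growth = isTRUE(an$growth),
              obs_days = an$obs_days %||% 70, dt = an$dt %||% 0.25,
              adult_age = an$adult_age %||% 35))
  cmp <- compare_models(sweeps)
  hdr <- .provenance_header(cfg)
  p_csv <- file.path(out_dir, "comparison.csv")
  .write_csv_with_header(cmp$table, p_csv, hdr)
  p_json <- file.path(out_dir, "exponents.json")
  jsonlite::write_json(
    c(list(config_hash = .config_hash(cfg)),
      stats::setNames(lapply(cmp$exponents, function(e)
        list(model_tag = e$model_tag, growth = e$growth,
             exponent = e$exponent, r2 = e$r2)),
        vapply(cmp$exponents, function(e) e$model_tag, ""))),
    p_json, auto_unbox = TRUE, digits = NA)
  p_cfg <- .echo_config(cfg, out_dir)
  invisible(list(comparison = cmp,
                 paths = c(comparison = p_csv, exponents = p_json,
                           config = p_cfg)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
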