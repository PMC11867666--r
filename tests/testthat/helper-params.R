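# Shared fixtures: parameter sets and cohorts built in code.

.fixture_env <- new.env(parent = emptyenv())

# Packaged defaults; the BSI gamma's scale is reconciled on load (warning
# expected), so cache one quiet copy for the whole suite.
base_params <- function() {
  if (is.null(.fixture_env$params)) {
    .fixture_env$params <- suppressWarnings(default_parameters())
  }
  .fixture_env$params
}

# Coarse, fast-absorbing parameters for engine tests: short stays and a
# visible BSI hazard so every pathway is exercised within a short horizon.
coarse_params <- function() {
  ps <- base_params()
  ps$mean_los_uti_days <- 1.5
  ps$los_ratio_resistant <- 4 / 3   # resistant mean LoS 2 days
  ps$mean_los_bsi_days <- 2
  ps$bsi_hourly_rate <- 2e-3
  ps$turnaround_culture_h <- 24
  ps$turnaround_bict_h <- 5
  ps$mortality_fraction_uti <- 0.1
  ps$mortality_ratio_resistant <- 2
  ps$mortality_fraction_bsi <- 0.3
  ps$horizon_h <- 600
  validate_parameter_set(ps)
  ps
}

small_cohort <- function(total = 1000) {
  build_cohort(total, base_params()$age_sex_weights)
}

# parameter set with a single all-cause hourly exit probability `h_exit`
# (death share `mf`), no BSI risk; used for closed-form checks
single_hazard_params <- function(h_exit, mf = 0) {
  ps <- base_params()
  daily <- 1 - (1 - h_exit)^24
  ps$mean_los_uti_days <- -1 / log(1 - daily)
  ps$los_ratio_resistant <- 1
  ps$mean_los_bsi_days <- ps$mean_los_uti_days
  ps$bsi_hourly_rate <- 0
  ps$mortality_fraction_uti <- mf
  ps$mortality_ratio_resistant <- 1
  ps$mortality_fraction_bsi <- mf
  validate_parameter_set(ps)
  ps
}

no_resistance_scenario <- function() {
  sc <- scenario_definition("base_population")
  sc$resistance_prevalence[] <- 0
  sc
}
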