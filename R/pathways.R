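#' Named analysis scenarios
#'
#' Four scenarios are registered. `base_population`: the full cohort, 5-hour
#' rapid test against 48-hour culture, empirical resistance 5\%
#' (nitrofurantoin, uncomplicated), 9\% (gentamicin, complicated IV) and
#' 13\% (cefalexin, complicated oral). `base_per_patient`: identical but a
#' cohort of size 1, yielding per-average-patient results.
#' `low_trimethoprim`: trimethoprim (5\% resistance) replaces nitrofurantoin
#' as the uncomplicated empirical choice. `high_resistance`: a hypothetical
#' 40\% resistance to every empirical antibiotic.
#'
#' Only resistance to the *empirical* antibiotic enters the model;
#' second-line resistance is deliberately not configurable.
#'
#' @param name One of `"base_population"`, `"base_per_patient"`,
#'   `"low_trimethoprim"`, `"high_resistance"`.
#' @return A `uti_scenario`: name, resistance prevalence map, cohort scale
#'   (`NA` = use the configured total; `1` = per-patient), and the
#'   uncomplicated empirical antibiotic.
#' @examples
#' scenario_definition("base_population")
#' @export
scenario_definition <- function(name) {
  defs <- list(
    base_population = list(
      resistance_prevalence = c(nitrofurantoin = 0.05, gentamicin = 0.09, cefalexin = 0.13),
      cohort_scale = NA_real_,
      uncomplicated_empirical = "nitrofurantoin"
    ),
    base_per_patient = list(
      resistance_prevalence = c(nitrofurantoin = 0.05, gentamicin = 0.09, cefalexin = 0.13),
      cohort_scale = 1,
      uncomplicated_empirical = "nitrofurantoin"
    ),
    low_trimethoprim = list(
      resistance_prevalence = c(trimethoprim = 0.05, gentamicin = 0.09, cefalexin = 0.13),
      cohort_scale = NA_real_,
      uncomplicated_empirical = "trimethoprim"
    ),
    high_resistance = list(
      resistance_prevalence = c(nitrofurantoin = 0.40, trimethoprim = 0.40,
                                gentamicin = 0.40, cefalexin = 0.40),
      cohort_scale = NA_real_,
      uncomplicated_empirical = "nitrofurantoin"
    )
  )
  if (!name %in% names(defs)) {
    stop("unknown scenario '", name, "'; known scenarios: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  sc <- defs[[name]]
  sc$name <- name
  if (any(sc$resistance_prevalence < 0) || any(sc$resistance_prevalence > 1)) {
    stop("scenario resistance prevalences must lie in [0, 1]", call. = FALSE)
  }
  class(sc) <- "uti_scenario"
  sc
}

#' @export
print.uti_scenario <- function(x, ...) {
  cat("<uti_scenario>", x$name,
      if (!is.na(x$cohort_scale)) sprintf("(cohort scale %g)", x$cohort_scale) else "", "\n")
  prev <- x$resistance_prevalence
  cat("  empirical resistance:",
      paste(sprintf("%s %.0f%%", names(prev), 100 * prev), collapse = ", "), "\n")
  invisible(x)
}

#' Resistance prevalence to an empirical antibiotic under a scenario
#'
#' @param scenario A `uti_scenario` (or its name).
#' @param antibiotic Antibiotic name present in the scenario's map.
#' @return The prevalence, in `[0, 1]`.
#' @examples
#' resistance_prevalence("base_population", "nitrofurantoin")
#' @export
resistance_prevalence <- function(scenario, antibiotic) {
  if (is.character(scenario)) scenario <- scenario_definition(scenario)
  stopifnot(inherits(scenario, "uti_scenario"))
  prev <- scenario$resistance_prevalence
  if (!antibiotic %in% names(prev)) {
    stop("no resistance prevalence for '", antibiotic, "' in scenario '",
         scenario$name, "'; known antibiotics: ",
         paste(names(prev), collapse = ", "), call. = FALSE)
  }
  unname(prev[[antibiotic]])
}

#' Antibiotic regimen for a stratum
#'
#' Deterministic treatment-pathway mapping, built from national prescribing
#' guidance: uncomplicated UTI receives oral nitrofurantoin empirically
#' (trimethoprim in the low-trimethoprim scenario) with pivmecillinam second
#' line; complicated UTI on the oral pathway receives cefalexin then
#' co-amoxiclav; complicated UTI on the intravenous pathway receives
#' gentamicin then co-amoxiclav IV. Age band and sex select the stratum but
#' do not alter the default regimen.
#'
#' @param age_band `"16-64"` or `"65-100"`.
#' @param sex `"F"` or `"M"`.
#' @param uti_type `"uncomplicated"`, `"complicated_oral"` or
#'   `"complicated_iv"`.
#' @param scenario A `uti_scenario` or scenario name.
#' @return A `regimen` list: `empirical_abx`, `second_line_abx`, `route`,
#'   and the daily drug-cost keys `cost_key_empirical`,
#'   `cost_key_second_line` into the `antibiotic_cost_day` parameter map.
#' @examples
#' assign_regimen("16-64", "M", "complicated_iv")
#' @export
assign_regimen <- function(age_band, sex, uti_type, scenario = "base_population") {
  if (is.character(scenario)) scenario <- scenario_definition(scenario)
  strata <- uti_strata()
  key <- paste(sex, age_band, uti_type, sep = ".")
  if (!key %in% strata$stratum) {
    stop("unknown stratum: age_band='", age_band, "', sex='", sex,
         "', uti_type='", uti_type, "'", call. = FALSE)
  }
  reg <- switch(uti_type,
    uncomplicated = list(
      empirical_abx = scenario$uncomplicated_empirical,
      second_line_abx = "pivmecillinam",
      route = "oral",
      cost_key_empirical = scenario$uncomplicated_empirical,
      cost_key_second_line = "pivmecillinam"
    ),
    complicated_oral = list(
      empirical_abx = "cefalexin",
      second_line_abx = "co-amoxiclav",
      route = "oral",
      cost_key_empirical = "cefalexin",
      cost_key_second_line = "coamoxiclav_oral"
    ),
    complicated_iv = list(
      empirical_abx = "gentamicin",
      second_line_abx = "co-amoxiclav",
      route = "intravenous",
      cost_key_empirical = "gentamicin_iv",
      cost_key_second_line = "coamoxiclav_iv"
    )
  )
  reg$stratum <- key
  class(reg) <- "regimen"
  reg
}

#' Regimen and resistance table for a whole cohort under a scenario
#'
#' @param scenario A `uti_scenario` or scenario name.
#' @return A 12-row `data.frame`: the strata, their regimens, and the
#'   resistance prevalence to each stratum's empirical antibiotic.
#' @export
regimen_table <- function(scenario = "base_population") {
  if (is.character(scenario)) scenario <- scenario_definition(scenario)
  strata <- uti_strata()
  regs <- lapply(seq_len(nrow(strata)), function(i) {
    r <- assign_regimen(strata$age_band[i], strata$sex[i], strata$uti_type[i], scenario)
    data.frame(
      empirical_abx = r$empirical_abx, second_line_abx = r$second_line_abx,
      route = r$route, cost_key_empirical = r$cost_key_empirical,
      cost_key_second_line = r$cost_key_second_line,
      stringsAsFactors = FALSE
    )
  })
  out <- cbind(strata, do.call(rbind, regs))
  out$resistance_prevalence <- vapply(
    out$empirical_abx, function(a) resistance_prevalence(scenario, a), numeric(1)
  )
  # Structural guard: the intravenous pathway must use the intravenous route
  stopifnot(all(out$route[out$uti_type == "complicated_iv"] == "intravenous"))
  rownames(out) <- NULL
  out
}
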