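#' Discounted QALY loss from a premature death
#'
#' A death in hospital forfeits the patient's remaining quality-adjusted
#' life expectancy. The loss is the annuity
#' \eqn{\sum_{t=0}^{\lceil L\rceil - 1} u/(1+d)^t} with the final partial
#' year prorated, where `L` is remaining life expectancy at the age-band
#' midpoint, `u` the baseline utility and `d` the annual discount rate.
#' Only this mortality component extends beyond one year, so it is the only
#' discounted quantity in the model.
#'
#' @param life_expectancy_remaining Remaining life expectancy in years
#'   (vectorised).
#' @param utility Baseline utility per life year.
#' @param annual_discount Annual discount rate (0.035 default).
#' @return Discounted QALYs lost per death.
#' @examples
#' qaly_loss_at_death(2, utility = 1, annual_discount = 0.035) # 1.96618
#' @export
qaly_loss_at_death <- function(life_expectancy_remaining, utility = 1,
                               annual_discount = 0.035) {
  if (any(life_expectancy_remaining < 0) || utility < 0 || annual_discount < 0) {
    stop("life expectancy, utility and discount rate must be non-negative", call. = FALSE)
  }
  v <- 1 / (1 + annual_discount)
  vapply(life_expectancy_remaining, function(L) {
    fy <- floor(L)
    full <- if (fy == 0) 0 else if (annual_discount == 0) fy else (1 - v^fy) / (1 - v)
    utility * (full + (L - fy) * v^fy)
  }, numeric(1))
}

#' Net monetary benefit
#'
#' \eqn{\mathrm{NMB} = \lambda \, \Delta \mathrm{QALY} - \Delta
#' \mathrm{Cost}} at willingness-to-pay \eqn{\lambda}. Positive NMB at the
#' threshold means the intervention is cost-effective; negative incremental
#' cost together with positive QALY gain means it dominates.
#'
#' @param delta_cost Incremental cost (intervention minus comparator), GBP.
#' @param delta_qaly Incremental QALY gain.
#' @param wtp Willingness to pay per QALY, GBP.
#' @return NMB in GBP (vectorised).
#' @export
compute_nmb <- function(delta_cost, delta_qaly, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * delta_qaly - delta_cost
}

# hourly blended bed cost per transient state for one stratum
.state_bed_rates <- function(params, uti_type) {
  prop_uti <- if (uti_type == "uncomplicated") params$prop_icu_uncomplicated else params$prop_icu_complicated
  uti_rate <- blended_bed_cost_hour(prop_uti, params$cost_bed_hour_general, params$cost_bed_hour_icu)
  bsi_rate <- blended_bed_cost_hour(params$prop_icu_bsi, params$cost_bed_hour_general, params$cost_bed_hour_icu)
  c(EMP_APPROPRIATE = uti_rate, EMP_INAPPROPRIATE = uti_rate,
    POST_APPROPRIATE = uti_rate, POST_INAPPROPRIATE = uti_rate,
    POST_FALSE_RESISTANT = uti_rate, BSI = bsi_rate)
}

#' Costs accrued by an occupancy trace
#'
#' Three components, all from the healthcare-system perspective in 2022
#' GBP: hospitalisation (state person-hours times the hourly bed cost,
#' blended between general ward and ICU by the state class's ICU
#' proportion), antibiotics (person-days in each state times the daily cost
#' of the drug being taken there: empirical agent before the result and
#' when resistance is missed, second-line agent after a resistant or
#' false-resistant result, BSI treatment in the BSI state), and diagnostics
#' (one test per patient entering the model, priced by arm).
#'
#' @param trace An `occupancy_trace`.
#' @param params A `parameter_set`.
#' @param by_stratum If `TRUE`, return the per-stratum cost matrix.
#' @return Total cost (GBP), or with `by_stratum = TRUE` a matrix with
#'   columns `bed`, `drugs`, `tests`, `total` and one row per stratum.
#' @export
accumulate_costs <- function(trace, params, by_stratum = FALSE) {
  stopifnot(inherits(trace, "occupancy_trace"), inherits(params, "parameter_set"))
  ph <- trace$person_hours
  regs <- trace$regimens
  drug_cost <- params$antibiotic_cost_day
  n_s <- nrow(regs)

  keys <- unique(c(regs$cost_key_empirical, regs$cost_key_second_line, "bsi_treatment"))
  missing <- setdiff(keys, names(drug_cost))
  if (length(missing)) {
    stop("no daily cost configured for drug(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  bed <- numeric(n_s)
  drugs <- numeric(n_s)
  for (i in seq_len(n_s)) {
    rates <- .state_bed_rates(params, regs$uti_type[i])
    bed[i] <- sum(ph[i, names(rates)] * rates)
    emp_days <- sum(ph[i, c("EMP_APPROPRIATE", "EMP_INAPPROPRIATE", "POST_INAPPROPRIATE")]) / 24
    second_days <- sum(ph[i, c("POST_APPROPRIATE", "POST_FALSE_RESISTANT")]) / 24
    bsi_days <- ph[i, "BSI"] / 24
    drugs[i] <- emp_days * drug_cost[[regs$cost_key_empirical[i]]] +
      second_days * drug_cost[[regs$cost_key_second_line[i]]] +
      bsi_days * drug_cost[["bsi_treatment"]]
  }
  test_price <- if (trace$arm == "bict") params$cost_bict_test else params$cost_standard_test
  tests <- trace$initial_mass * test_price

  m <- cbind(bed = bed, drugs = drugs, tests = unname(tests))
  m <- cbind(m, total = rowSums(m))
  rownames(m) <- trace$strata
  if (by_stratum) m else sum(m[, "total"])
}

#' QALYs lost over an occupancy trace
#'
#' Morbidity: person-hours in UTI states times the hourly UTI decrement,
#' plus person-hours in the BSI state times the hourly BSI decrement
#' (within one year, undiscounted). Mortality: each death loses the
#' discounted remaining quality-adjusted life expectancy at the stratum's
#' age-band midpoint ([qaly_loss_at_death()]).
#'
#' @param trace An `occupancy_trace`.
#' @param params A `parameter_set`.
#' @param by_stratum If `TRUE`, return the per-stratum vector.
#' @return Total QALYs lost (a non-negative number; fewer lost is better).
#' @export
accumulate_qalys <- function(trace, params, by_stratum = FALSE) {
  stopifnot(inherits(trace, "occupancy_trace"), inherits(params, "parameter_set"))
  ph <- trace$person_hours
  uti_states <- c("EMP_APPROPRIATE", "EMP_INAPPROPRIATE", "POST_APPROPRIATE",
                  "POST_INAPPROPRIATE", "POST_FALSE_RESISTANT")
  morb <- rowSums(ph[, uti_states, drop = FALSE]) * params$qaly_decrement_uti_hour +
    ph[, "BSI"] * params$qaly_decrement_bsi_hour
  band_key <- paste0("age_", gsub("-", "_", trace$regimens$age_band))
  L <- params$life_expectancy_years[band_key]
  loss_per_death <- qaly_loss_at_death(L, params$utility_norm, params$discount_rate_annual)
  mort <- trace$absorbed_dead * loss_per_death
  v <- morb + mort
  names(v) <- trace$strata
  if (by_stratum) v else sum(v)
}

#' Economic summary of one model arm
#'
#' @param trace An `occupancy_trace`.
#' @param params A `parameter_set`.
#' @return An `econ_result`: totals (`total_cost`, `total_qalys_lost`,
#'   `bed_days`, `inappropriate_days`, `bsi_person_days`, `deaths`), the
#'   cost components, and a per-stratum `data.frame`.
#' @export
econ_result <- function(trace, params) {
  cost_m <- accumulate_costs(trace, params, by_stratum = TRUE)
  qalys <- accumulate_qalys(trace, params, by_stratum = TRUE)
  per_stratum <- data.frame(
    stratum = trace$strata,
    cost = unname(cost_m[, "total"]),
    qalys_lost = unname(qalys),
    bed_days = unname(bed_days(trace, by_stratum = TRUE)),
    inappropriate_days = unname(inappropriate_person_days(trace, by_stratum = TRUE)),
    bsi_person_days = unname(bsi_person_days(trace, by_stratum = TRUE)),
    deaths = unname(model_deaths(trace, by_stratum = TRUE)),
    stringsAsFactors = FALSE
  )
  total <- sum(cost_m[, "total"])
  comp <- colSums(cost_m[, c("bed", "drugs", "tests"), drop = FALSE])
  stopifnot(abs(total - sum(comp)) <= 1e-6 * max(total, 1))
  structure(list(
    arm = trace$arm, scenario = trace$scenario,
    total_cost = total, cost_components = comp,
    total_qalys_lost = sum(qalys),
    bed_days = sum(per_stratum$bed_days),
    inappropriate_days = sum(per_stratum$inappropriate_days),
    bsi_person_days = sum(per_stratum$bsi_person_days),
    deaths = sum(per_stratum$deaths),
    per_stratum = per_stratum
  ), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat("<econ_result>", x$arm, "arm,", x$scenario, "\n")
  cat(sprintf("  cost £%.0f (bed %.0f, drugs %.0f, tests %.0f); QALYs lost %.2f\n",
              x$total_cost, x$cost_components[["bed"]], x$cost_components[["drugs"]],
              x$cost_components[["tests"]], x$total_qalys_lost))
  cat(sprintf("  bed days %.1f; inappropriate days %.1f; BSI days %.2f; deaths %.2f\n",
              x$bed_days, x$inappropriate_days, x$bsi_person_days, x$deaths))
  invisible(x)
}

#' Incremental comparison of the rapid-test arm against culture
#'
#' @param econ_culture,econ_bict `econ_result` objects for the two arms on
#'   the same cohort and parameters.
#' @param wtp Willingness to pay per QALY.
#' @return An `incremental_result`: `delta_cost` (bict minus culture),
#'   `delta_qaly` (QALY gain of bict over culture), `nmb`, and a
#'   `dominant` flag (cost-saving and QALY-gaining, at least one strictly).
#' @export
incremental_result <- function(econ_culture, econ_bict, wtp) {
  stopifnot(inherits(econ_culture, "econ_result"), inherits(econ_bict, "econ_result"))
  delta_cost <- econ_bict$total_cost - econ_culture$total_cost
  delta_qaly <- econ_culture$total_qalys_lost - econ_bict$total_qalys_lost
  structure(list(
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    nmb = compute_nmb(delta_cost, delta_qaly, wtp),
    wtp = wtp,
    dominant = (delta_cost <= 0 && delta_qaly >= 0) && (delta_cost < 0 || delta_qaly > 0)
  ), class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> ΔCost £%.0f, ΔQALY %.3f, NMB £%.0f at £%s/QALY%s\n",
              x$delta_cost, x$delta_qaly, x$nmb, format(x$wtp, big.mark = " "),
              if (x$dominant) " (dominant)" else ""))
  invisible(x)
}
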