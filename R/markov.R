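#' Health states of the hourly Markov model
#'
#' Six transient in-hospital states and two absorbing states. On admission a
#' patient is on empirical antibiotics, either effective
#' (`EMP_APPROPRIATE`: pathogen susceptible) or not (`EMP_INAPPROPRIATE`:
#' pathogen resistant and prescribing inappropriate). When the
#' susceptibility result arrives, resistant patients are switched to
#' effective second-line therapy (`POST_APPROPRIATE`) unless the test
#' misses the resistance (`POST_INAPPROPRIATE`); susceptible patients stay
#' on empirical therapy unless a false-resistant result switches them
#' unnecessarily (`POST_FALSE_RESISTANT`). Every in-hospital UTI state can
#' progress to bloodstream infection (`BSI`); every in-hospital state can
#' exit to discharge alive (`WELL`) or death (`DEAD`).
#'
#' @return Character vector of the eight state names, transient states
#'   first.
#' @export
markov_states <- function() {
  c("EMP_APPROPRIATE", "EMP_INAPPROPRIATE", "POST_APPROPRIATE",
    "POST_INAPPROPRIATE", "POST_FALSE_RESISTANT", "BSI", "WELL", "DEAD")
}

.TRANSIENT <- 1:6
.ABSORBING <- 7:8
.INAPPROPRIATE_STATES <- c("EMP_INAPPROPRIATE", "POST_INAPPROPRIATE")
# exit-profile class backing each transient state
.STATE_CLASS <- c(
  EMP_APPROPRIATE = "susceptible_appropriate",
  EMP_INAPPROPRIATE = "resistant_inappropriate",
  POST_APPROPRIATE = "susceptible_appropriate",
  POST_INAPPROPRIATE = "resistant_inappropriate",
  POST_FALSE_RESISTANT = "susceptible_appropriate",
  BSI = "bsi"
)

#' Hourly transition matrix for one arm
#'
#' Builds the 8 x 8 row-stochastic matrix of hourly transition
#' probabilities. Competing risks within a row (result arrival, BSI onset,
#' discharge alive, death) are additive on the hourly scale; the stay
#' probability takes the remainder. In the default `"deterministic"` mode
#' the matrix carries no result transitions and [run_cohort()] applies the
#' result allocation as a one-off event at the turnaround hour (each
#' patient is tested once and the result arrives at a fixed time), so the
#' `pre_result` and `post_result` phase matrices coincide. In `"rate"` mode
#' the result instead arrives as a memoryless hourly hazard `1/turnaround`
#' (mean delay equal to the turnaround time); note that, because a
#' susceptible result leaves the patient in the empirical state, the
#' memoryless hazard re-exposes susceptible patients to the
#' false-resistant misallocation at every arrival, which overstates
#' unnecessary switching for long stays and short turnarounds.
#'
#' @param params A `parameter_set`.
#' @param arm `"culture"` or `"bict"`; selects the turnaround time.
#' @param mode `"deterministic"` (default) or `"rate"` result arrival.
#' @param phase Phase tag attached in deterministic mode.
#' @return A `transition_matrix`: the matrix with attributes `arm`, `mode`,
#'   `phase`. Every row sums to one to within 1e-12 and absorbing rows are
#'   identity.
#' @export
build_transition_matrix <- function(params, arm = c("culture", "bict"),
                                    mode = c("deterministic", "rate"),
                                    phase = c("pre_result", "post_result")) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  phase <- match.arg(phase)
  stopifnot(inherits(params, "parameter_set"))

  states <- markov_states()
  profile <- exit_profile_from_params(params)
  rownames(profile) <- profile$state_class
  hourly_exit <- daily_prob_to_hourly_prob(profile$daily_discharge_prob)
  names(hourly_exit) <- profile$state_class
  death_frac <- stats::setNames(profile$death_fraction, profile$state_class)

  p_bsi <- hourly_rate_to_prob(params$bsi_hourly_rate)
  turnaround <- if (arm == "culture") params$turnaround_culture_h else params$turnaround_bict_h
  p_res <- if (mode == "rate") hourly_rate_to_prob(1 / turnaround) else 0
  sens <- params$test_sensitivity
  spec <- params$test_specificity

  P <- matrix(0, 8, 8, dimnames = list(states, states))
  add <- function(from, to, p) P[from, to] <<- P[from, to] + p

  for (s in states[.TRANSIENT]) {
    cls <- .STATE_CLASS[[s]]
    exit <- hourly_exit[[cls]]
    add(s, "WELL", exit * (1 - death_frac[[cls]]))
    add(s, "DEAD", exit * death_frac[[cls]])
    if (s != "BSI") add(s, "BSI", p_bsi)
  }
  # result arrival (rate mode): allocation conditional on the result
  add("EMP_APPROPRIATE", "POST_FALSE_RESISTANT", p_res * (1 - spec))
  add("EMP_INAPPROPRIATE", "POST_APPROPRIATE", p_res * sens)
  add("EMP_INAPPROPRIATE", "POST_INAPPROPRIATE", p_res * (1 - sens))

  for (s in states[.TRANSIENT]) {
    off <- sum(P[s, ]) - P[s, s]
    if (off > 1) {
      stop("competing risks leaving state ", s, " sum to ", format(off),
           " > 1; use shorter cycles or smaller hazards", call. = FALSE)
    }
    P[s, s] <- 1 - off
  }
  P["WELL", "WELL"] <- 1
  P["DEAD", "DEAD"] <- 1

  structure(P, class = c("transition_matrix", "matrix"),
            arm = arm, mode = mode, phase = if (mode == "deterministic") phase else "single")
}

#' Allocate cohort mass on arrival of the susceptibility result
#'
#' Resistant mass is recognised with probability `sensitivity` and switched
#' to effective second-line therapy (`POST_APPROPRIATE`); the remainder is
#' missed (`POST_INAPPROPRIATE`). Susceptible mass stays on empirical
#' therapy with probability `specificity`; the remainder is falsely called
#' resistant and switched unnecessarily (`POST_FALSE_RESISTANT`). Total
#' mass is conserved.
#'
#' @param resistant_mass,susceptible_mass Non-negative cohort masses in the
#'   empirical states when the result arrives.
#' @param sensitivity,specificity Test operating characteristics in
#'   `[0, 1]`.
#' @return Named numeric vector over `POST_APPROPRIATE`,
#'   `POST_INAPPROPRIATE`, `POST_FALSE_RESISTANT` and `EMP_APPROPRIATE`
#'   (mass remaining on empirical therapy).
#' @examples
#' result_allocation(100, 0, 0.95, 0.85)
#' @export
result_allocation <- function(resistant_mass, susceptible_mass, sensitivity, specificity) {
  if (resistant_mass < 0 || susceptible_mass < 0) {
    stop("masses must be non-negative", call. = FALSE)
  }
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  c(
    POST_APPROPRIATE = resistant_mass * sensitivity,
    POST_INAPPROPRIATE = resistant_mass * (1 - sensitivity),
    POST_FALSE_RESISTANT = susceptible_mass * (1 - specificity),
    EMP_APPROPRIATE = susceptible_mass * specificity
  )
}

# 8x8 linear map applying result_allocation to the empirical states,
# identity elsewhere; used for the deterministic-arrival event.
.allocation_matrix <- function(sens, spec) {
  states <- markov_states()
  A <- diag(8)
  dimnames(A) <- list(states, states)
  A["EMP_APPROPRIATE", "EMP_APPROPRIATE"] <- spec
  A["EMP_APPROPRIATE", "POST_FALSE_RESISTANT"] <- 1 - spec
  A["EMP_INAPPROPRIATE", "EMP_INAPPROPRIATE"] <- 0
  A["EMP_INAPPROPRIATE", "POST_APPROPRIATE"] <- sens
  A["EMP_INAPPROPRIATE", "POST_INAPPROPRIATE"] <- 1 - sens
  A
}

#' Propagate a cohort through the Markov model to absorption
#'
#' Each stratum's mass enters on empirical therapy, split between the
#' appropriate and inappropriate states by the product of resistance
#' prevalence (to that stratum's empirical antibiotic, under the scenario)
#' and the inappropriate-prescribing proportion. Mass is then propagated
#' hour by hour until the horizon; occupancy (person-hours per stratum and
#' state) and absorptions are recorded. Mass conservation is checked at
#' every cycle to 1e-9 relative tolerance and any transient mass remaining
#' at the horizon is force-discharged alive (and recorded).
#'
#' With `method = "analytic"` the same expected occupancy is obtained in
#' closed form from the fundamental matrix of the absorbing chain,
#' \eqn{N = (I - Q)^{-1}}: in rate mode person-hours are `initial \%*\% N`
#' and absorptions `initial \%*\% N \%*\% R`; in deterministic mode the
#' geometric sum is split at the turnaround hour, the result allocation
#' applied to the transient mass there, and the post-result tail summed to
#' absorption. This is the infinite-horizon limit of the hourly iteration
#' and is used where many runs are needed (probabilistic and one-way
#' sensitivity analysis).
#'
#' @param cohort A `cohort_table`.
#' @param params A `parameter_set`.
#' @param arm `"culture"` or `"bict"`.
#' @param scenario A `uti_scenario` or scenario name (supplies resistance
#'   prevalences and the uncomplicated empirical antibiotic).
#' @param mode `"deterministic"` or `"rate"` result arrival, see
#'   [build_transition_matrix()].
#' @param method `"iterate"` (hour-by-hour) or `"analytic"` (fundamental
#'   matrix).
#' @param horizon Simulation horizon in hours.
#' @param keep_trace If `TRUE` (iterate only), retain the full
#'   hour-by-hour occupancy array (`(horizon + 1) x strata x states`).
#' @return An `occupancy_trace`: per-stratum person-hours by transient
#'   state, absorbed-alive/dead masses, forced discharges, the regimen
#'   table used, and optionally the full trace array.
#' @export
run_cohort <- function(cohort, params, arm = c("culture", "bict"),
                       scenario = "base_population",
                       mode = c("deterministic", "rate"),
                       method = c("iterate", "analytic"),
                       horizon = params$horizon_h,
                       keep_trace = FALSE) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort_table"), inherits(params, "parameter_set"))
  if (is.character(scenario)) scenario <- scenario_definition(scenario)
  states <- markov_states()
  n_s <- nrow(cohort)

  regs <- regimen_table(scenario)
  # align regimen rows with the cohort's stratum order
  regs <- regs[match(cohort$stratum, regs$stratum), ]
  prev_ri <- resistant_inappropriate_prevalence(
    regs$resistance_prevalence, params$inappropriate_rx_proportion
  )
  O <- matrix(0, n_s, 8, dimnames = list(cohort$stratum, states))
  O[, "EMP_INAPPROPRIATE"] <- cohort$count * prev_ri
  O[, "EMP_APPROPRIATE"] <- cohort$count * (1 - prev_ri)
  initial_mass <- cohort$count

  P <- build_transition_matrix(params, arm, mode)
  person_hours <- matrix(0, n_s, 6, dimnames = list(cohort$stratum, states[.TRANSIENT]))

  if (method == "analytic") {
    Q <- P[.TRANSIENT, .TRANSIENT]
    R <- P[.TRANSIENT, .ABSORBING]
    N <- solve(diag(6) - Q)
    O_T <- O[, .TRANSIENT, drop = FALSE]
    if (mode == "deterministic") {
      t_alloc <- as.integer(round(
        if (arm == "culture") params$turnaround_culture_h else params$turnaround_bict_h
      ))
      QT <- diag(6)
      for (k in seq_len(t_alloc)) QT <- QT %*% Q   # Q^turnaround, small exponent
      pre_hours <- O_T %*% (N %*% (diag(6) - QT))  # occupancy over hours [0, turnaround)
      A6 <- .allocation_matrix(params$test_sensitivity, params$test_specificity)[.TRANSIENT, .TRANSIENT]
      post_mass <- (O_T %*% QT) %*% A6
      person_hours <- pre_hours + post_mass %*% N
    } else {
      person_hours <- O_T %*% N
    }
    absorbed <- person_hours %*% R
    out <- list(
      absorbed_alive = absorbed[, "WELL"], absorbed_dead = absorbed[, "DEAD"],
      forced_discharge = stats::setNames(numeric(n_s), cohort$stratum),
      trace = NULL, horizon = Inf
    )
  } else {
    t_alloc <- if (mode == "deterministic") {
      as.integer(round(if (arm == "culture") params$turnaround_culture_h else params$turnaround_bict_h))
    } else NA_integer_
    A <- if (mode == "deterministic") .allocation_matrix(params$test_sensitivity, params$test_specificity)
    trace <- if (keep_trace) array(
      NA_real_, dim = c(horizon + 1L, n_s, 8L),
      dimnames = list(NULL, cohort$stratum, states)
    )
    tol <- 1e-9 * pmax(initial_mass, 1)
    for (t in 0:(horizon - 1L)) {
      if (!is.na(t_alloc) && t == t_alloc) O <- O %*% A
      if (keep_trace) trace[t + 1L, , ] <- O
      person_hours <- person_hours + O[, .TRANSIENT, drop = FALSE]
      O <- O %*% P
      if (any(abs(.rowSums(O, n_s, 8L) - initial_mass) > tol)) {
        stop("internal consistency error: cohort mass not conserved at cycle ", t,
             call. = FALSE)
      }
    }
    if (keep_trace) trace[horizon + 1L, , ] <- O
    leftover <- rowSums(O[, .TRANSIENT, drop = FALSE])
    if (sum(leftover) > 1e-6 * max(sum(initial_mass), 1)) {
      message(sprintf(
        "%.3g cohort mass (%.2g of initial) still in transient states at the %d-hour horizon; force-discharged alive",
        sum(leftover), sum(leftover) / max(sum(initial_mass), 1e-300), horizon
      ))
    }
    out <- list(
      absorbed_alive = O[, "WELL"] + leftover, absorbed_dead = O[, "DEAD"],
      forced_discharge = leftover, trace = trace, horizon = horizon
    )
  }

  structure(
    c(list(
      strata = cohort$stratum, initial_mass = stats::setNames(initial_mass, cohort$stratum),
      person_hours = person_hours, regimens = regs, arm = arm,
      scenario = scenario$name, mode = mode, method = method
    ), out),
    class = "occupancy_trace"
  )
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat("<occupancy_trace>", x$arm, "arm,", x$scenario, "scenario,",
      x$mode, "mode,", x$method, "method\n")
  cat(sprintf("  cohort %.6g; bed days %.6g; inappropriate days %.6g; deaths %.6g\n",
              sum(x$initial_mass), bed_days(x), inappropriate_person_days(x),
              sum(x$absorbed_dead)))
  invisible(x)
}

#' Summary measures of an occupancy trace
#'
#' `inappropriate_person_days()`: person-days on an empirical antibiotic the
#' pathogen is resistant to (states `EMP_INAPPROPRIATE` and
#' `POST_INAPPROPRIATE`). `bed_days()`: person-days across all in-hospital
#' states. `bsi_person_days()`: person-days in the bloodstream-infection
#' state. `model_deaths()`: total absorbed deaths.
#'
#' @param trace An `occupancy_trace`.
#' @param by_stratum If `TRUE`, return the per-stratum vector instead of
#'   the total.
#' @return Days (or deaths), total or per stratum.
#' @export
inappropriate_person_days <- function(trace, by_stratum = FALSE) {
  stopifnot(inherits(trace, "occupancy_trace"))
  v <- rowSums(trace$person_hours[, .INAPPROPRIATE_STATES, drop = FALSE]) / 24
  if (by_stratum) v else sum(v)
}

#' @rdname inappropriate_person_days
#' @export
bed_days <- function(trace, by_stratum = FALSE) {
  stopifnot(inherits(trace, "occupancy_trace"))
  v <- rowSums(trace$person_hours) / 24
  if (by_stratum) v else sum(v)
}

#' @rdname inappropriate_person_days
#' @export
bsi_person_days <- function(trace, by_stratum = FALSE) {
  stopifnot(inherits(trace, "occupancy_trace"))
  v <- trace$person_hours[, "BSI"] / 24
  if (by_stratum) v else sum(v)
}

#' @rdname inappropriate_person_days
#' @export
model_deaths <- function(trace, by_stratum = FALSE) {
  stopifnot(inherits(trace, "occupancy_trace"))
  v <- trace$absorbed_dead
  if (by_stratum) v else sum(v)
}
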