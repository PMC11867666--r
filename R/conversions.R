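#' Rate and probability conversions
#'
#' The Markov model runs on one-hour cycles, while inputs arrive on other
#' time scales: a cumulative risk over a follow-up window (bloodstream
#' infection per admission), daily discharge probabilities derived from
#' length-of-stay, and turnaround times in hours. These helpers perform the
#' standard constant-hazard conversions between them.
#'
#' `cumulative_prob_to_hourly_rate()` converts a cumulative probability `p`
#' observed over `window_h` hours into a constant per-hour rate,
#' \eqn{-\log(1-p)/w}. `daily_prob_to_hourly_prob()` converts a daily
#' probability into the hourly probability that compounds back to it over 24
#' hours, \eqn{1-(1-p)^{1/24}}. `hourly_rate_to_prob()` is the per-cycle
#' probability of an event with constant hourly rate `r`, \eqn{1-e^{-r}}.
#'
#' @param p Cumulative probability over the window, in `[0, 1)`.
#' @param window_h Window length in hours, strictly positive.
#' @param p_daily Daily probability in `[0, 1]`.
#' @param r Non-negative hourly rate.
#'
#' @return A numeric vector (vectorised over the probability/rate argument).
#' @examples
#' cumulative_prob_to_hourly_rate(1253 / 280462, 60 * 24) # per-hour BSI rate
#' daily_prob_to_hourly_prob(0.2)
#' @export
cumulative_prob_to_hourly_rate <- function(p, window_h) {
  if (!is.numeric(p) || any(p < 0) || any(p >= 1)) {
    stop("`p` must be a cumulative probability in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(window_h) || length(window_h) != 1L || window_h <= 0) {
    stop("`window_h` must be a single positive number of hours", call. = FALSE)
  }
  -log1p(-p) / window_h
}

#' @rdname cumulative_prob_to_hourly_rate
#' @export
daily_prob_to_hourly_prob <- function(p_daily) {
  if (!is.numeric(p_daily) || any(p_daily < 0) || any(p_daily > 1)) {
    stop("`p_daily` must be a probability in [0, 1]", call. = FALSE)
  }
  1 - (1 - p_daily)^(1 / 24)
}

#' @rdname cumulative_prob_to_hourly_rate
#' @export
hourly_rate_to_prob <- function(r) {
  if (!is.numeric(r) || any(r < 0)) {
    stop("`r` must be a non-negative hourly rate", call. = FALSE)
  }
  -expm1(-r)
}

#' Blended hourly bed cost across general ward and intensive care
#'
#' Intensive-care use is modelled as a cost blend rather than a separate
#' health state: a state class occupying an ICU bed with probability
#' `prop_icu` costs the weighted average of the two hourly bed rates.
#'
#' @param prop_icu Proportion of the state class cared for in ICU, in `[0, 1]`.
#' @param c_general,c_icu Hourly cost (GBP) of a general and an ICU bed.
#' @return Blended hourly cost in GBP.
#' @examples
#' blended_bed_cost_hour(0.139, 24.6, 85.07)
#' @export
blended_bed_cost_hour <- function(prop_icu, c_general, c_icu) {
  if (!is.numeric(prop_icu) || any(prop_icu < 0) || any(prop_icu > 1)) {
    stop("`prop_icu` must be a proportion in [0, 1]", call. = FALSE)
  }
  if (any(c_general < 0) || any(c_icu < 0)) {
    stop("bed costs must be non-negative", call. = FALSE)
  }
  (1 - prop_icu) * c_general + prop_icu * c_icu
}
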