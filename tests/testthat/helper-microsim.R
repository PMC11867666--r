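# Independent patient-level Monte-Carlo oracle for the cohort engine.
# Transition sampling is written from scratch against the model's hazards
# (it shares no code path with run_cohort): each simulated patient moves
# hour by hour between the states
#   1 EMP_APPROPRIATE  2 EMP_INAPPROPRIATE  3 POST_APPROPRIATE
#   4 POST_INAPPROPRIATE  5 POST_FALSE_RESISTANT  6 BSI  7 WELL  8 DEAD
# Returns per-patient mean person-hours by transient state with Monte-Carlo
# standard errors, plus the death fraction.
microsim_person_hours <- function(ps, prev_inapp, n, turnaround, horizon,
                                  mode = c("deterministic", "rate"), seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)

  hourly_from_los <- function(los_days) {
    daily <- 1 - exp(-1 / los_days)
    1 - (1 - daily)^(1 / 24)
  }
  h_sus <- hourly_from_los(ps$mean_los_uti_days)
  h_res <- hourly_from_los(ps$mean_los_uti_days * ps$los_ratio_resistant)
  h_bsi <- hourly_from_los(ps$mean_los_bsi_days)
  mf_sus <- ps$mortality_fraction_uti
  mf_res <- min(1, ps$mortality_fraction_uti * ps$mortality_ratio_resistant)
  mf_bsi <- ps$mortality_fraction_bsi
  p_bsi <- 1 - exp(-ps$bsi_hourly_rate)
  p_res <- 1 - exp(-1 / turnaround)
  sens <- ps$test_sensitivity
  spec <- ps$test_specificity

  # per-state hourly exit hazards (exit prob, death share, bsi prob)
  exit_p <- c(h_sus, h_res, h_sus, h_res, h_sus, h_bsi)
  death_share <- c(mf_sus, mf_res, mf_sus, mf_res, mf_sus, mf_bsi)
  bsi_p <- c(p_bsi, p_bsi, p_bsi, p_bsi, p_bsi, 0)

  state <- ifelse(stats::runif(n) < prev_inapp, 2L, 1L)
  ph <- matrix(0, n, 6)
  for (t in 0:(horizon - 1L)) {
    if (mode == "deterministic" && t == turnaround) {
      i1 <- which(state == 1L)
      state[i1] <- ifelse(stats::runif(length(i1)) < spec, 1L, 5L)
      i2 <- which(state == 2L)
      state[i2] <- ifelse(stats::runif(length(i2)) < sens, 3L, 4L)
    }
    alive <- which(state <= 6L)
    if (!length(alive)) break
    ph[cbind(alive, state[alive])] <- ph[cbind(alive, state[alive])] + 1
    u <- stats::runif(length(alive))
    s <- state[alive]
    new_s <- s
    p1 <- bsi_p[s]                      # -> BSI
    p2 <- p1 + exit_p[s] * (1 - death_share[s])  # -> WELL
    p3 <- p2 + exit_p[s] * death_share[s]        # -> DEAD
    new_s[u < p1] <- 6L
    new_s[u >= p1 & u < p2] <- 7L
    new_s[u >= p2 & u < p3] <- 8L
    if (mode == "rate") {
      # memoryless result arrival competes after the clinical events
      res_a <- u >= p3 & u < p3 + p_res & s %in% c(1L, 2L)
      if (any(res_a)) {
        v <- stats::runif(sum(res_a))
        src <- s[res_a]
        tgt <- integer(sum(res_a))
        tgt[src == 1L] <- ifelse(v[src == 1L] < spec, 1L, 5L)
        tgt[src == 2L] <- ifelse(v[src == 2L] < sens, 3L, 4L)
        new_s[res_a] <- tgt
      }
    }
    state[alive] <- new_s
  }
  list(
    mean = colMeans(ph),
    se = apply(ph, 2, stats::sd) / sqrt(n),
    death_mean = mean(state == 8L),
    death_se = stats::sd(state == 8L) / sqrt(n),
    n = n
  )
}

# Single-stratum cohort: all mass in one stratum, zero elsewhere.
one_stratum_cohort <- function(stratum, mass = 1) {
  ch <- build_cohort(1, base_params()$age_sex_weights)
  ch$count <- ifelse(ch$stratum == stratum, mass, 0)
  ch
}
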