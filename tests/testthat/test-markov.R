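test_that("the state space has six transient and two absorbing states", {
  s <- markov_states()
  expect_length(s, 8)
  expect_equal(tail(s, 2), c("WELL", "DEAD"))
})

test_that("every built transition matrix is row-stochastic with entries in [0,1]", {
  for (ps in list(base_params(), coarse_params())) {
    for (arm in c("culture", "bict")) {
      for (mode in c("deterministic", "rate")) {
        P <- build_transition_matrix(ps, arm, mode)
        expect_true(all(P >= 0 & P <= 1))
        expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-12)
        expect_equal(unname(P["WELL", ]), c(rep(0, 6), 1, 0))
        expect_equal(unname(P["DEAD", ]), c(rep(0, 7), 1))
      }
    }
  }
  # and for sampled parameter draws
  for (i in 1:10) {
    ps <- sample_parameter_set(base_params(), seed = 300 + i)
    P <- build_transition_matrix(ps, "bict", "rate")
    expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("with all hazards switched off the matrix is the identity", {
  ps <- base_params()
  ps$mean_los_uti_days <- 1e12
  ps$mean_los_bsi_days <- 1e12
  ps$los_ratio_resistant <- 1
  ps$bsi_hourly_rate <- 0
  P <- build_transition_matrix(ps, "culture", "deterministic")
  expect_lt(max(abs(P - diag(8))), 1e-9)
})

test_that("competing risks exceeding one are refused with the state named", {
  ps <- coarse_params()
  ps$mean_los_uti_days <- 0.01
  ps$bsi_hourly_rate <- 5
  expect_error(build_transition_matrix(ps, "culture"), "competing risks")
})

test_that("result allocation splits mass by sensitivity and specificity and conserves it", {
  a <- result_allocation(100, 0, 0.95, 0.85)
  expect_equal(a[["POST_APPROPRIATE"]], 95)
  expect_equal(a[["POST_INAPPROPRIATE"]], 5)
  b <- result_allocation(0, 100, 0.95, 1.0)
  expect_equal(b[["EMP_APPROPRIATE"]], 100)
  expect_equal(b[["POST_FALSE_RESISTANT"]], 0)
  c_ <- result_allocation(100, 100, 1, 1)
  expect_equal(c_[["POST_INAPPROPRIATE"]], 0)
  expect_equal(c_[["POST_FALSE_RESISTANT"]], 0)
  for (i in 1:10) {
    set.seed(i)
    m <- runif(2, 0, 50); sn <- runif(1); sp <- runif(1)
    expect_equal(sum(result_allocation(m[1], m[2], sn, sp)), sum(m), tolerance = 1e-12)
  }
  expect_error(result_allocation(-1, 0, 0.9, 0.9), "non-negative")
  expect_error(result_allocation(1, 1, 1.2, 0.9), "\\[0, 1\\]")
})

test_that("a single exit hazard decays geometrically: survival and expected stay", {
  # all-cause exit 0.012/h (alive 0.01, dead 0.002): P(in hospital at 24h) = 0.988^24
  ps <- single_hazard_params(0.012, mf = 0.002 / 0.012)
  ch <- small_cohort(100)
  tr <- run_cohort(ch, ps, "culture", no_resistance_scenario(),
                   horizon = 3000, keep_trace = TRUE)
  in_hosp_24 <- sum(tr$trace[25, , 1:6])
  expect_equal(in_hosp_24, 100 * (1 - 0.012)^24, tolerance = 1e-9)

  # discharge-only hazard 0.01/h, N = 100: total person-hours -> N/p = 10000
  ps2 <- single_hazard_params(0.01, mf = 0)
  tr2 <- run_cohort(ch, ps2, "culture", no_resistance_scenario(), horizon = 3000)
  expect_equal(sum(tr2$person_hours), 100 / 0.01, tolerance = 1e-6)
  expect_equal(bed_days(tr2), 10000 / 24, tolerance = 1e-6)
  expect_equal(model_deaths(tr2), 0, tolerance = 1e-12)
})

test_that("cohort mass is conserved at every cycle and absorbed by the horizon", {
  ps <- coarse_params()
  ch <- small_cohort(1000)
  tr <- run_cohort(ch, ps, "culture", horizon = 600, keep_trace = TRUE)
  totals <- apply(tr$trace, 1, function(m) rowSums(m))  # strata x hours
  err <- abs(totals - ch$count) / pmax(ch$count, 1)
  expect_lt(max(err), 1e-9)
  expect_true(all(tr$trace >= 0))
  leftover <- sum(tr$trace[601, , 1:6])
  expect_lt(leftover, 1e-6 * sum(ch$count))
  expect_equal(sum(tr$absorbed_alive) + sum(tr$absorbed_dead), sum(ch$count),
               tolerance = 1e-9)
})

test_that("hour-by-hour iteration agrees with the fundamental-matrix solution", {
  ps <- coarse_params()
  ch <- small_cohort(500)
  for (mode in c("deterministic", "rate")) {
    for (arm in c("culture", "bict")) {
      it <- run_cohort(ch, ps, arm, mode = mode, method = "iterate", horizon = 1200)
      an <- run_cohort(ch, ps, arm, mode = mode, method = "analytic")
      expect_equal(it$person_hours, an$person_hours, tolerance = 1e-8)
      expect_equal(sum(it$absorbed_dead), sum(an$absorbed_dead), tolerance = 1e-8)
    }
  }
})

test_that("days on inappropriate therapy follow the deterministic-arrival law", {
  ps <- base_params()
  ps$mean_los_uti_days <- 1e9        # no exits on the test's time scale
  ps$mean_los_bsi_days <- 1e9
  ps$los_ratio_resistant <- 1
  ps$bsi_hourly_rate <- 0
  ps$test_sensitivity <- 1           # nobody is missed
  ch <- small_cohort(1000)
  regs <- regimen_table("base_population")
  m0 <- sum(ch$count * regs$resistance_prevalence[match(ch$stratum, regs$stratum)] *
              ps$inappropriate_rx_proportion)

  run48 <- function(tat) {
    ps$turnaround_culture_h <- tat
    suppressMessages(run_cohort(ch, ps, "culture", horizon = 100))
  }
  tr48 <- run48(48)
  expect_equal(inappropriate_person_days(tr48), m0 * 48 / 24, tolerance = 1e-9)
  # halving the turnaround exactly halves the inappropriate days
  tr24 <- run48(24)
  expect_equal(inappropriate_person_days(tr48), 2 * inappropriate_person_days(tr24),
               tolerance = 1e-9)
  # zero resistance prevalence gives zero inappropriate days
  tr0 <- suppressMessages(run_cohort(ch, ps, "culture", no_resistance_scenario(),
                                     horizon = 100))
  expect_equal(inappropriate_person_days(tr0), 0)
})

test_that("an empty cohort produces an all-zero trace", {
  ch <- small_cohort(1000)
  ch$count[] <- 0
  tr <- run_cohort(ch, coarse_params(), "bict", horizon = 200)
  expect_equal(sum(tr$person_hours), 0)
  expect_equal(bed_days(tr), 0)
  expect_equal(model_deaths(tr), 0)
})

test_that("the rapid arm never does worse on inappropriate days, bed days or deaths", {
  ps <- coarse_params()
  ch <- small_cohort(1000)
  for (mode in c("deterministic", "rate")) {
    cu <- run_cohort(ch, ps, "culture", mode = mode, horizon = 600)
    bi <- run_cohort(ch, ps, "bict", mode = mode, horizon = 600)
    expect_lt(inappropriate_person_days(bi), inappropriate_person_days(cu))
    expect_lte(bed_days(bi), bed_days(cu))
    expect_lte(model_deaths(bi), model_deaths(cu))
    expect_lte(bsi_person_days(bi), bsi_person_days(cu))
  }
})
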