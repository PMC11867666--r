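# minimal hand-built occupancy trace for unit costing checks
fake_trace <- function(hours_by_state, arm = "culture", deaths = 0,
                       uti_type = "uncomplicated", age_band = "65-100") {
  ph <- matrix(0, 1, 6, dimnames = list("s1", markov_states()[1:6]))
  ph[1, names(hours_by_state)] <- hours_by_state
  structure(list(
    strata = "s1", initial_mass = c(s1 = 1), person_hours = ph,
    regimens = data.frame(uti_type = uti_type, age_band = age_band,
                          cost_key_empirical = "nitrofurantoin",
                          cost_key_second_line = "pivmecillinam",
                          stringsAsFactors = FALSE),
    absorbed_alive = c(s1 = 1 - deaths), absorbed_dead = c(s1 = deaths),
    forced_discharge = c(s1 = 0), arm = arm, scenario = "base_population",
    mode = "deterministic", method = "iterate", horizon = 100
  ), class = "occupancy_trace")
}

test_that("a day on a general ward costs 24 hours at the hourly bed rate", {
  ps <- base_params()
  ps$antibiotic_cost_day[] <- 0
  ps$cost_standard_test <- 0
  tr <- fake_trace(c(EMP_APPROPRIATE = 24))
  expect_equal(accumulate_costs(tr, ps), 24 * 24.6, tolerance = 1e-9)  # £590.40
})

test_that("cost components add up: bed, drugs and one test per patient", {
  ps <- base_params()
  tr <- fake_trace(c(EMP_APPROPRIATE = 24, POST_APPROPRIATE = 24, BSI = 12))
  m <- accumulate_costs(tr, ps, by_stratum = TRUE)
  drug <- ps$antibiotic_cost_day
  expect_equal(m[1, "drugs"],
               drug[["nitrofurantoin"]] + drug[["pivmecillinam"]] +
                 0.5 * drug[["bsi_treatment"]], tolerance = 1e-12)
  expect_equal(m[1, "tests"], ps$cost_standard_test)
  expect_equal(m[1, "total"], sum(m[1, c("bed", "drugs", "tests")]), tolerance = 1e-12)
  # BSI bed hours are costed at the BSI ICU blend
  bsi_rate <- blended_bed_cost_hour(ps$prop_icu_bsi, ps$cost_bed_hour_general,
                                    ps$cost_bed_hour_icu)
  uti_rate <- ps$cost_bed_hour_general  # uncomplicated: no ICU
  expect_equal(m[1, "bed"], 48 * uti_rate + 12 * bsi_rate, tolerance = 1e-9)
  # complicated strata use the complicated ICU blend
  trc <- fake_trace(c(EMP_APPROPRIATE = 24), uti_type = "complicated_oral")
  mc <- accumulate_costs(trc, ps, by_stratum = TRUE)
  expect_equal(mc[1, "bed"],
               24 * blended_bed_cost_hour(ps$prop_icu_complicated,
                                          ps$cost_bed_hour_general,
                                          ps$cost_bed_hour_icu), tolerance = 1e-9)
  ps_missing <- ps
  ps_missing$antibiotic_cost_day <- ps$antibiotic_cost_day["cefalexin"]
  expect_error(accumulate_costs(fake_trace(c(EMP_APPROPRIATE = 1)), ps_missing),
               "no daily cost")
})

test_that("diagnostic cost is identical in both arms at test-price parity", {
  ps <- base_params()
  expect_equal(ps$cost_bict_test, ps$cost_standard_test)
  mc <- accumulate_costs(fake_trace(c(EMP_APPROPRIATE = 10), arm = "culture"),
                         ps, by_stratum = TRUE)
  mb <- accumulate_costs(fake_trace(c(EMP_APPROPRIATE = 10), arm = "bict"),
                         ps, by_stratum = TRUE)
  expect_equal(mc[1, "tests"], mb[1, "tests"])
})

test_that("the discounted QALY loss at death follows the annuity closed form", {
  expect_equal(qaly_loss_at_death(0), 0)
  expect_equal(qaly_loss_at_death(2, 1, 0.035), 1 + 1 / 1.035, tolerance = 1e-9)
  expect_equal(qaly_loss_at_death(2, 1, 0.035), 1.96618, tolerance = 1e-5)
  expect_equal(qaly_loss_at_death(7.5, 1, 0), 7.5)            # undiscounted limit
  expect_equal(qaly_loss_at_death(2.5, 0.8, 0.035),
               0.8 * (1 + 1 / 1.035 + 0.5 / 1.035^2), tolerance = 1e-12)
  expect_error(qaly_loss_at_death(-1), "non-negative")
})

test_that("QALY losses decompose into morbidity and mortality parts", {
  ps <- base_params()
  # zero decrements and no deaths: no loss
  ps0 <- ps
  ps0$qaly_decrement_uti_hour <- 0
  ps0$qaly_decrement_bsi_hour <- 0
  expect_equal(accumulate_qalys(fake_trace(c(EMP_APPROPRIATE = 100)), ps0), 0)
  # one death loses exactly the discounted life expectancy at the band midpoint
  tr1 <- fake_trace(c(EMP_APPROPRIATE = 0), deaths = 1)
  expected <- qaly_loss_at_death(ps$life_expectancy_years[["age_65_100"]],
                                 ps$utility_norm, ps$discount_rate_annual)
  expect_equal(accumulate_qalys(tr1, ps0), expected, tolerance = 1e-12)
  # doubling deaths doubles the mortality component
  tr2 <- fake_trace(c(EMP_APPROPRIATE = 0), deaths = 2)
  expect_equal(accumulate_qalys(tr2, ps0), 2 * expected, tolerance = 1e-12)
  # morbidity part is hours times the hourly decrement
  trm <- fake_trace(c(EMP_INAPPROPRIATE = 48, BSI = 24))
  expect_equal(accumulate_qalys(trm, ps),
               48 * ps$qaly_decrement_uti_hour + 24 * ps$qaly_decrement_bsi_hour,
               tolerance = 1e-12)
})

test_that("net monetary benefit is the exact linear identity", {
  expect_equal(compute_nmb(0, 0, 20000), 0)
  expect_equal(compute_nmb(-606138, 186, 20000), 4326138)
  expect_equal(compute_nmb(-6826894, 1175, 20000), 30326894)
  expect_error(compute_nmb(1, 1, -5), "non-negative")
})

test_that("incremental results carry the NMB identity and the dominance flag", {
  ps <- coarse_params()
  ch <- small_cohort(400)
  cu <- econ_result(run_cohort(ch, ps, "culture", horizon = 600), ps)
  bi <- econ_result(run_cohort(ch, ps, "bict", horizon = 600), ps)
  inc <- incremental_result(cu, bi, ps$wtp)
  expect_equal(inc$nmb, ps$wtp * inc$delta_qaly - inc$delta_cost)
  expect_equal(inc$delta_cost, bi$total_cost - cu$total_cost)
  expect_equal(inc$delta_qaly, cu$total_qalys_lost - bi$total_qalys_lost)
  # identical arms: no dominance, all zeros
  same <- incremental_result(cu, cu, ps$wtp)
  expect_identical(same$delta_cost, 0)
  expect_false(same$dominant)
  # cheaper and more effective: dominant
  expect_true(incremental_result(cu, bi, ps$wtp)$dominant ==
                (inc$delta_cost <= 0 && inc$delta_qaly >= 0 &&
                   (inc$delta_cost < 0 || inc$delta_qaly > 0)))
  # econ totals are non-negative and components sum
  expect_gte(cu$total_cost, 0)
  expect_gte(cu$total_qalys_lost, 0)
  expect_equal(cu$total_cost, sum(cu$cost_components), tolerance = 1e-9)
})
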