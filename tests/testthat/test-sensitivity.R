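psa_fixture <- function(delta_cost, delta_qaly, wtp = 20000) {
  structure(
    data.frame(draw = seq_along(delta_cost), draw_seed = seq_along(delta_cost),
               delta_cost = delta_cost, delta_qaly = delta_qaly,
               nmb = wtp * delta_qaly - delta_cost),
    class = c("psa_results", "data.frame"), seed = 0L, wtp = wtp,
    scenario = "base_population", redraws = 0L
  )
}

test_that("the PSA is reproducible under a fixed seed", {
  ps <- coarse_params()
  ch <- small_cohort(300)
  a <- run_psa(n = 20, seed = 7, cohort = ch, params = ps)
  b <- run_psa(n = 20, seed = 7, cohort = ch, params = ps)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- run_psa(n = 20, seed = 8, cohort = ch, params = ps)
  expect_false(identical(a$nmb, c_$nmb))
})

test_that("with all distributions fixed one PSA draw equals the deterministic run", {
  ps <- coarse_params()
  attr(ps, "dists") <- Filter(Negate(is.null), stats::setNames(lapply(
    seq_along(ps), function(i) if (length(ps[[i]]) == 1L) dist_fixed(ps[[i]])
  ), names(ps)))
  ch <- small_cohort(300)
  psa <- run_psa(n = 1, seed = 3, cohort = ch, params = ps)
  det <- run_scenario("base_population", cohort = ch, params = ps,
                      method = "analytic")
  expect_equal(psa$delta_cost, det$incremental$delta_cost)
  expect_equal(psa$delta_qaly, det$incremental$delta_qaly)
})

test_that("the acceptability curve matches exhaustive enumeration on a hand-built draw set", {
  psa <- psa_fixture(delta_cost = c(-10, 10, 10, -10),
                     delta_qaly = c(1, 1, -1, -2))
  curve <- ceac(psa, lambda_grid = c(0, 5, 30))
  expect_equal(curve$probability, c(0.5, 0.25, 0.5))
  # lambda = 0: exactly the share of cost-saving draws
  expect_equal(ceac(psa, 0)$probability, mean(psa$delta_cost < 0))
  # lambda -> infinity: the share of QALY-gaining draws
  expect_equal(ceac(psa, 1e12)$probability, mean(psa$delta_qaly > 0))
  expect_error(ceac(psa, numeric(0)), "non-empty")
})

test_that("uniformly dominant draws are accepted at every threshold", {
  psa <- psa_fixture(delta_cost = c(-5, -1, -3), delta_qaly = c(0.1, 0.2, 0.3))
  curve <- ceac(psa, lambda_grid = seq(0, 50000, by = 10000))
  expect_true(all(curve$probability == 1))
})

test_that("acceptability at the threshold is stable as draws double", {
  ps <- coarse_params()
  ch <- small_cohort(300)
  p1 <- run_psa(n = 40, seed = 11, cohort = ch, params = ps)
  p2 <- run_psa(n = 80, seed = 12, cohort = ch, params = ps)
  f1 <- ceac(p1, 20000)$probability
  f2 <- ceac(p2, 20000)$probability
  se <- sqrt(f1 * (1 - f1) / 40 + f2 * (1 - f2) / 80)
  expect_lte(abs(f1 - f2), max(2 * se, 1e-12))
})

test_that("the tornado ranks one-way parameter effects and respects supports", {
  ps <- coarse_params()
  ch <- small_cohort(300)
  ranges <- list(
    test_sensitivity = c(0.75, 1.0),
    cost_bict_test = c(11.7525, 19.5875),
    mortality_ratio_resistant = c(1.0, 2.5),
    utility_norm = c(0.8, 0.8),                 # zero-width range
    turnaround_bict_h = c(1, ps$turnaround_culture_h),
    resistance_prevalence_scale = c(0.5, 2)
  )
  tt <- tornado(ps, "base_population", param_ranges = ranges, cohort = ch)
  expect_s3_class(tt, "tornado_table")
  expect_true(all(diff(tt$spread) <= 1e-12))     # sorted by influence
  expect_equal(tt$spread[tt$parameter == "utility_norm"], 0)
  # a rapid test as slow as culture brings no benefit at all
  expect_equal(tt$nmb_high[tt$parameter == "turnaround_bict_h"], 0,
               tolerance = 1e-9)
  expect_error(tornado(ps, "base_population", cohort = ch,
                       param_ranges = list(test_sensitivity = c(0.5, 1.5))),
               "outside its support")
})

test_that("widening a monotone parameter's range never shrinks its bar", {
  ps <- coarse_params()
  ch <- small_cohort(300)
  narrow <- tornado(ps, "base_population", cohort = ch,
                    param_ranges = list(resistance_prevalence_scale = c(0.8, 1.2)))
  wide <- tornado(ps, "base_population", cohort = ch,
                  param_ranges = list(resistance_prevalence_scale = c(0.5, 2)))
  expect_gte(wide$spread, narrow$spread)
})

test_that("plot builders return ggplot objects", {
  psa <- psa_fixture(delta_cost = rnorm(20, -5), delta_qaly = rnorm(20, 0.1, 0.02))
  expect_s3_class(plot_ce_plane(psa), "ggplot")
  expect_s3_class(plot_ceac(ceac(psa, seq(0, 30000, 5000))), "ggplot")
  ps <- coarse_params()
  tt <- tornado(ps, "base_population", cohort = small_cohort(100),
                param_ranges = list(test_sensitivity = c(0.75, 1)))
  expect_s3_class(plot_tornado(tt), "ggplot")
})
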