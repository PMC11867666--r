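#' Probabilistic sensitivity analysis
#'
#' Draws `n` parameter sets from the configured uncertainty distributions
#' ([sample_parameter_set()]), runs the full paired scenario for each draw,
#' and records the incremental cost, incremental QALY gain and net monetary
#' benefit. Per-draw seeds are derived from the root seed and the draw
#' index by a fixed counter scheme, so any single draw can be reproduced in
#' isolation and the whole analysis is reproducible given `(n, seed)`.
#'
#' Draws whose model run fails an internal-consistency check are discarded
#' and redrawn under a perturbed seed; the count of such redraws is
#' recorded in the `redraws` attribute.
#'
#' @param n Number of draws (1000 default).
#' @param seed Root integer seed.
#' @param scenario Scenario name or `uti_scenario`.
#' @param cohort Optional `cohort_table`; defaults to the cohort implied by
#'   `params`.
#' @param params Base `parameter_set` supplying the distributions.
#' @param method Propagation method passed to [run_cohort()]; the analytic
#'   fundamental-matrix route is the default since each draw needs a full
#'   paired evaluation.
#' @return A `psa_results` `data.frame` with columns `draw`, `draw_seed`,
#'   `delta_cost`, `delta_qaly`, `nmb`, and attributes `seed`, `wtp`,
#'   `scenario`, `redraws`.
#' @export
run_psa <- function(n = 1000L, seed = 1L, scenario = "base_population",
                    cohort = NULL, params = default_parameters(),
                    method = c("analytic", "iterate")) {
  method <- match.arg(method)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  n <- as.integer(n)
  if (is.character(scenario)) scenario <- scenario_definition(scenario)
  if (is.null(cohort)) cohort <- build_cohort(params$total_cohort, params$age_sex_weights)

  draw_seed <- function(i, attempt = 0L) {
    as.integer((as.double(seed) * 1009 + as.double(i) * 9973 + attempt * 7919) %% 2147483629)
  }
  rows <- vector("list", n)
  redraws <- 0L
  for (i in seq_len(n)) {
    attempt <- 0L
    repeat {
      res <- tryCatch({
        ps_i <- suppressMessages(sample_parameter_set(params, draw_seed(i, attempt)))
        run_scenario(scenario, cohort = cohort, params = ps_i, method = method)
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      redraws <- redraws + 1L
      if (attempt > 100L) {
        stop("draw ", i, " failed repeatedly: ", conditionMessage(res), call. = FALSE)
      }
    }
    rows[[i]] <- data.frame(
      draw = i, draw_seed = draw_seed(i, attempt),
      delta_cost = res$incremental$delta_cost,
      delta_qaly = res$incremental$delta_qaly,
      nmb = res$incremental$nmb
    )
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("psa_results", "data.frame"),
            seed = seed, wtp = params$wtp, scenario = scenario$name,
            redraws = redraws)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value \eqn{\lambda} on the grid, the
#' fraction of PSA draws with positive net monetary benefit
#' \eqn{\lambda\,\Delta q - \Delta c > 0}. At \eqn{\lambda = 0} this is the
#' share of cost-saving draws; as \eqn{\lambda \to \infty} it approaches
#' the share of QALY-gaining draws.
#'
#' @param psa A `psa_results` object.
#' @param lambda_grid Non-negative willingness-to-pay grid (GBP/QALY).
#' @return A `ceacurve` `data.frame` with columns `lambda`, `probability`.
#' @export
ceac <- function(psa, lambda_grid = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(psa, "psa_results"))
  if (length(lambda_grid) == 0L || any(lambda_grid < 0)) {
    stop("`lambda_grid` must be a non-empty grid of non-negative values", call. = FALSE)
  }
  prob <- vapply(lambda_grid, function(l) {
    mean(compute_nmb(psa$delta_cost, psa$delta_qaly, l) > 0)
  }, numeric(1))
  structure(data.frame(lambda = lambda_grid, probability = prob),
            class = c("ceacurve", "data.frame"))
}

#' One-way (tornado) sensitivity analysis on net monetary benefit
#'
#' Re-evaluates the paired scenario with one parameter at a time set to the
#' low and high end of its range, everything else held at base values.
#' Default ranges come from each parameter's uncertainty distribution
#' (uniforms contribute their bounds, gammas their central 95\% interval).
#' Two structural quantities can be varied through reserved names:
#' `turnaround_bict_h` (the rapid test's turnaround) and
#' `resistance_prevalence_scale` (a multiplier applied to every empirical
#' resistance prevalence in the scenario, capped at 1).
#'
#' @param params Base `parameter_set`.
#' @param scenario Scenario name or `uti_scenario`.
#' @param param_ranges Named list of `c(low, high)` ranges; `NULL` uses the
#'   defaults described above plus `turnaround_bict_h` over `(1, turnaround
#'   culture)` and `resistance_prevalence_scale` over `(0.5, 2)`.
#' @param cohort Optional `cohort_table`.
#' @param method Propagation method for each evaluation.
#' @return A `tornado_table` `data.frame` (`parameter`, `low`, `high`,
#'   `nmb_low`, `nmb_high`, `spread`), sorted by decreasing spread, with
#'   the base-case NMB in the `base_nmb` attribute.
#' @export
tornado <- function(params = default_parameters(), scenario = "base_population",
                    param_ranges = NULL, cohort = NULL,
                    method = c("analytic", "iterate")) {
  method <- match.arg(method)
  if (is.character(scenario)) scenario <- scenario_definition(scenario)
  if (is.null(cohort)) cohort <- build_cohort(params$total_cohort, params$age_sex_weights)

  if (is.null(param_ranges)) {
    dists <- attr(params, "dists")
    varied <- names(dists)[vapply(dists, function(d) d$kind != "fixed", logical(1))]
    param_ranges <- lapply(stats::setNames(varied, varied),
                           function(nm) dist_interval(dists[[nm]]))
    param_ranges$turnaround_bict_h <- c(1, params$turnaround_culture_h)
    param_ranges$resistance_prevalence_scale <- c(0.5, 2)
  }

  eval_nmb <- function(nm, value) {
    ps <- params
    sc <- scenario
    if (nm == "resistance_prevalence_scale") {
      sc$resistance_prevalence[] <- pmin(1, sc$resistance_prevalence * value)
    } else {
      if (!nm %in% names(ps)) stop("unknown tornado parameter '", nm, "'", call. = FALSE)
      b <- .param_bounds(nm)
      if (value < b[1] || value > b[2]) {
        stop(sprintf("range endpoint %g for '%s' outside its support [%g, %g]",
                     value, nm, b[1], b[2]), call. = FALSE)
      }
      ps[[nm]] <- value
      validate_parameter_set(ps)
    }
    run_scenario(sc, cohort = cohort, params = ps, method = method)$incremental$nmb
  }

  base_nmb <- run_scenario(scenario, cohort = cohort, params = params,
                           method = method)$incremental$nmb
  rows <- lapply(names(param_ranges), function(nm) {
    r <- param_ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop("range for '", nm, "' must be c(low, high) with low <= high", call. = FALSE)
    }
    data.frame(parameter = nm, low = r[1], high = r[2],
               nmb_low = eval_nmb(nm, r[1]), nmb_high = eval_nmb(nm, r[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$nmb_high - out$nmb_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  structure(out, class = c("tornado_table", "data.frame"), base_nmb = base_nmb)
}
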