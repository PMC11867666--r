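#' Model parameter sets
#'
#' A `parameter_set` holds every model input as a named value (scalar or
#' named map), together with the uncertainty distribution attached to each
#' scalar parameter. The packaged default configuration
#' (`system.file("extdata", "parameters.yaml", package = "bictcea")`)
#' carries the published point estimates and distributions; values only
#' available from restricted sources are synthetic placeholders and say so
#' in their `source` field.
#'
#' @param path Path to a YAML parameter configuration.
#' @return A `parameter_set`: a named list of values with attributes
#'   `dists` (named list of [dist_gamma()]-family objects) and `meta`
#'   (units and source strings).
#' @examples
#' ps <- default_parameters()
#' ps$wtp
#' ps$turnaround_bict_h
#' @export
default_parameters <- function() {
  read_parameters(system.file("extdata", "parameters.yaml", package = "bictcea"))
}

#' @rdname default_parameters
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  values <- list()
  dists <- list()
  meta <- list()
  for (nm in names(raw)) {
    entry <- raw[[nm]]
    if (!is.list(entry) || is.null(entry$value)) {
      stop("parameter '", nm, "' must be a mapping with a `value` field", call. = FALSE)
    }
    v <- entry$value
    if (is.list(v)) v <- unlist(v)  # named map parameter
    values[[nm]] <- v
    if (!is.null(entry$distribution)) {
      dists[[nm]] <- .parse_dist(entry$distribution, nm)
    } else if (length(v) == 1L && is.numeric(v)) {
      dists[[nm]] <- dist_fixed(v)
    }
    meta[[nm]] <- list(units = entry$units %||% "", source = entry$source %||% "")
  }
  ps <- structure(values, class = "parameter_set", dists = dists, meta = meta)
  ps <- .reconcile_gamma_means(ps)
  validate_parameter_set(ps)
  ps
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_dist <- function(d, nm) {
  kind <- d$kind %||% stop("distribution for '", nm, "' lacks `kind`", call. = FALSE)
  switch(kind,
    gamma   = dist_gamma(d$shape, d$scale),
    uniform = dist_uniform(d$min, d$max),
    fixed   = dist_fixed(d$value),
    stop("unknown distribution kind '", kind, "' for parameter '", nm, "'", call. = FALSE)
  )
}

# A printed gamma whose mean is wildly off the point estimate (an order of
# magnitude or more, as happens when a scale is reported where an inverse
# rate was meant) keeps its shape -- and hence its dispersion -- but has its
# scale reset so the distribution mean equals the point estimate. The PSA
# then stays centred on the deterministic model.
.reconcile_gamma_means <- function(ps) {
  dists <- attr(ps, "dists")
  for (nm in names(dists)) {
    d <- dists[[nm]]
    v <- ps[[nm]]
    if (d$kind == "gamma" && length(v) == 1L && v > 0) {
      ratio <- dist_mean(d) / v
      if (ratio > 10 || ratio < 0.1) {
        new_scale <- v / d$shape
        warning(sprintf(
          "gamma distribution for '%s' has mean %.4g, %.3g times its point estimate %.4g; rescaling scale %.4g -> %.4g to centre the distribution on the point estimate",
          nm, dist_mean(d), ratio, v, d$scale, new_scale
        ), call. = FALSE)
        dists[[nm]] <- dist_gamma(d$shape, new_scale)
      }
    }
  }
  attr(ps, "dists") <- dists
  ps
}

# Structural bounds by parameter, intersected with distribution support when
# sampling. Proportions live in [0,1]; the inappropriate-prescribing share
# is constrained to its literature range; LoS ratios may not fall below 1
# (resistant stays are never shorter than susceptible ones).
.param_bounds <- function(nm) {
  proportions <- c(
    "test_sensitivity", "test_specificity", "prop_icu_complicated",
    "prop_icu_uncomplicated", "prop_icu_bsi", "mortality_fraction_uti",
    "mortality_fraction_bsi", "utility_norm"
  )
  if (nm %in% proportions) return(c(0, 1))
  if (nm == "inappropriate_rx_proportion") return(c(0.20, 0.35))
  if (nm == "los_ratio_resistant") return(c(1, Inf))
  if (nm == "mortality_ratio_resistant") return(c(0, Inf))
  if (nm %in% c("mean_los_uti_days", "mean_los_bsi_days")) return(c(1e-9, Inf))
  c(0, Inf)  # rates, costs, counts, decrements: non-negative
}

#' Validate a parameter set
#'
#' Checks the structural invariants every model run relies on: proportions
#' in `[0, 1]`, non-negative costs and rates, a rapid-test turnaround
#' strictly shorter than culture, a horizon longer than the slower
#' turnaround, age-sex weights summing to one, and derived death fractions
#' not exceeding one.
#'
#' @param ps A `parameter_set`.
#' @return `ps`, invisibly; errors describe the first violated invariant.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  for (nm in names(ps)) {
    v <- ps[[nm]]
    if (!is.numeric(v)) stop("parameter '", nm, "' is not numeric", call. = FALSE)
    b <- .param_bounds(nm)
    if (length(v) == 1L && (v < b[1] || v > b[2])) {
      stop(sprintf("parameter '%s' = %g outside its allowed range [%g, %g]",
                   nm, v, b[1], b[2]), call. = FALSE)
    }
  }
  if (any(ps$antibiotic_cost_day < 0)) {
    stop("antibiotic daily costs must be non-negative", call. = FALSE)
  }
  # equality permitted: identical turnarounds give the equal-arms null model
  if (ps$turnaround_bict_h > ps$turnaround_culture_h) {
    stop("rapid-test turnaround must not exceed the culture turnaround", call. = FALSE)
  }
  if (ps$horizon_h <= max(ps$turnaround_culture_h, ps$turnaround_bict_h)) {
    stop("horizon must exceed the slower turnaround time", call. = FALSE)
  }
  w <- ps$age_sex_weights
  if (abs(sum(w) - 1) > 1e-6 || any(w < 0)) {
    stop("age_sex_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (ps$mortality_fraction_uti * ps$mortality_ratio_resistant > 1) {
    stop("resistant death fraction (mortality_fraction_uti * mortality_ratio_resistant) exceeds 1", call. = FALSE)
  }
  invisible(ps)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Replaces every parameter carrying a non-degenerate distribution with one
#' independent draw from it. Draws that violate a structural bound (for
#' example a sampled proportion above one) are rejected and redrawn; the
#' number of rejections is recorded in the `rejections` attribute of the
#' result and reported with a message. An identical seed reproduces the
#' identical draw.
#'
#' @param base A validated `parameter_set` supplying distributions.
#' @param seed Integer seed for the draw; `NULL` uses the current RNG state.
#' @param max_redraws Cap on rejections per parameter before erroring.
#' @return A new `parameter_set` with sampled values.
#' @export
sample_parameter_set <- function(base, seed = NULL, max_redraws = 1000L) {
  stopifnot(inherits(base, "parameter_set"))
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
    set.seed(as.integer(seed))
  }
  dists <- attr(base, "dists")
  out <- base
  rejections <- 0L
  for (nm in names(dists)) {
    d <- dists[[nm]]
    if (d$kind == "fixed") next
    b <- .param_bounds(nm)
    draw <- dist_sample(d)
    tries <- 0L
    while (draw < b[1] || draw > b[2]) {
      tries <- tries + 1L
      if (tries > max_redraws) {
        stop("could not draw '", nm, "' inside [", b[1], ", ", b[2], "] after ",
             max_redraws, " redraws", call. = FALSE)
      }
      draw <- dist_sample(d)
    }
    rejections <- rejections + tries
    out[[nm]] <- draw
  }
  attr(out, "rejections") <- rejections
  if (rejections > 0L) {
    message(rejections, " out-of-support draw(s) rejected and redrawn")
  }
  validate_parameter_set(out)
  out
}

#' Audit table of all parameters
#'
#' One row per scalar parameter (map-valued parameters contribute one row
#' per entry): name, point value, distribution, and whether the point value
#' lies inside the distribution's support.
#'
#' @param ps A `parameter_set`.
#' @return A `data.frame` with columns `parameter`, `value`, `distribution`,
#'   `support_low`, `support_high`, `in_support`, `units`.
#' @export
parameter_audit <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  dists <- attr(ps, "dists")
  meta <- attr(ps, "meta")
  rows <- list()
  for (nm in names(ps)) {
    v <- ps[[nm]]
    units <- meta[[nm]]$units %||% ""
    if (length(v) == 1L) {
      d <- dists[[nm]] %||% dist_fixed(v)
      s <- dist_support(d)
      rows[[nm]] <- data.frame(
        parameter = nm, value = unname(v), distribution = format(d),
        support_low = s[1], support_high = s[2],
        in_support = v >= s[1] && v <= s[2], units = units,
        stringsAsFactors = FALSE
      )
    } else {
      rows[[nm]] <- data.frame(
        parameter = paste(nm, names(v), sep = "."), value = unname(v),
        distribution = "Fixed (map entry)", support_low = unname(v),
        support_high = unname(v), in_support = TRUE, units = units,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  n_dist <- sum(vapply(attr(x, "dists"), function(d) d$kind != "fixed", logical(1)))
  cat("<parameter_set>", length(x), "parameters,", n_dist, "with uncertainty distributions\n")
  cat("  turnaround: culture", x$turnaround_culture_h, "h, rapid test",
      x$turnaround_bict_h, "h; WTP £", format(x$wtp, big.mark = " "), "/QALY\n")
  invisible(x)
}
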