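#' Uncertainty distributions for model parameters
#'
#' Every model input carries a point estimate and, where uncertainty is
#' propagated in the probabilistic sensitivity analysis, a distribution.
#' Three families are supported: gamma (shape/scale, used for rates and
#' costs), uniform (used for proportions and for parameters with assumed
#' plus/minus 25\% ranges), and fixed (degenerate, excluded from sampling).
#'
#' @param shape,scale Gamma shape and scale, both strictly positive.
#' @param min,max Uniform bounds, `min <= max`.
#' @param value The single value of a degenerate (fixed) distribution.
#'
#' @return An object of class `param_dist`.
#' @examples
#' dist_uniform(0.75, 1.00)
#' dist_gamma(0.39, 8e-6)
#' @export
dist_gamma <- function(shape, scale) {
  stopifnot(is.numeric(shape), is.numeric(scale), length(shape) == 1L, length(scale) == 1L)
  if (shape <= 0 || scale <= 0) {
    stop("gamma distribution requires shape > 0 and scale > 0", call. = FALSE)
  }
  structure(list(kind = "gamma", shape = shape, scale = scale), class = "param_dist")
}

#' @rdname dist_gamma
#' @export
dist_uniform <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), length(min) == 1L, length(max) == 1L)
  if (min > max) stop("uniform distribution requires min <= max", call. = FALSE)
  structure(list(kind = "uniform", min = min, max = max), class = "param_dist")
}

#' @rdname dist_gamma
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  structure(list(kind = "fixed", value = value), class = "param_dist")
}

#' @export
print.param_dist <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.param_dist <- function(x, ...) {
  switch(x$kind,
    gamma   = sprintf("Gamma(shape = %g, scale = %g)", x$shape, x$scale),
    uniform = sprintf("Uniform(%g, %g)", x$min, x$max),
    fixed   = sprintf("Fixed(%g)", x$value)
  )
}

#' Sample from a parameter distribution
#'
#' @param dist A `param_dist` object.
#' @param n Number of independent draws.
#' @return Numeric vector of length `n`, always inside the distribution's
#'   support.
#' @export
dist_sample <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "param_dist"))
  switch(dist$kind,
    gamma   = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    uniform = stats::runif(n, min = dist$min, max = dist$max),
    fixed   = rep(dist$value, n)
  )
}

#' Support of a parameter distribution
#'
#' @param dist A `param_dist` object.
#' @return Length-2 numeric vector `c(lower, upper)`.
#' @export
dist_support <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  switch(dist$kind,
    gamma   = c(0, Inf),
    uniform = c(dist$min, dist$max),
    fixed   = c(dist$value, dist$value)
  )
}

#' Mean of a parameter distribution
#'
#' @param dist A `param_dist` object.
#' @return The distribution mean.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  switch(dist$kind,
    gamma   = dist$shape * dist$scale,
    uniform = (dist$min + dist$max) / 2,
    fixed   = dist$value
  )
}

#' Central interval of a parameter distribution
#'
#' Used to derive default one-way (tornado) sensitivity ranges: uniform
#' distributions contribute their full range, gammas their central 95\%
#' interval, fixed values a zero-width range.
#'
#' @param dist A `param_dist` object.
#' @param level Coverage of the central interval for unbounded families.
#' @return Length-2 numeric vector `c(low, high)`.
#' @export
dist_interval <- function(dist, level = 0.95) {
  stopifnot(inherits(dist, "param_dist"))
  a <- (1 - level) / 2
  switch(dist$kind,
    gamma   = stats::qgamma(c(a, 1 - a), shape = dist$shape, scale = dist$scale),
    uniform = c(dist$min, dist$max),
    fixed   = c(dist$value, dist$value)
  )
}

# Uniform with bounds at +/- 25% of a point estimate; the convention used
# for parameters whose uncertainty was assumed rather than estimated.
#' @rdname dist_gamma
#' @param value Point estimate around which the plus/minus 25\% band is taken.
#' @export
dist_uniform_pm25 <- function(value) {
  dist_uniform(0.75 * value, 1.25 * value)
}
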