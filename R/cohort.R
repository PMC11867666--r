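#' The twelve patient strata
#'
#' Admissions are stratified by age band (16-64, 65-100), sex, and UTI type
#' (uncomplicated, complicated with oral treatment, complicated with
#' intravenous treatment): 2 x 2 x 3 = 12 strata. The stratum determines the
#' antibiotic regimen and the QALY loss attached to a death; resistance
#' prevalence and lengths of stay are shared across strata.
#'
#' @return A 12-row `data.frame` with columns `age_band`, `sex`, `uti_type`
#'   and a `stratum` label.
#' @export
uti_strata <- function() {
  g <- expand.grid(
    uti_type = c("uncomplicated", "complicated_oral", "complicated_iv"),
    sex = c("F", "M"),
    age_band = c("16-64", "65-100"),
    stringsAsFactors = FALSE
  )[, c("age_band", "sex", "uti_type")]
  g$stratum <- paste(g$sex, g$age_band, g$uti_type, sep = ".")
  g
}

#' Build a synthetic admission cohort
#'
#' Generates the cohort table the analysis runs on, emulating the structure
#' of national hospital admissions data (which is access-restricted): a
#' total cohort mass is split across sex and age band by `age_sex_weights`,
#' and within each sex-age group into 80\% uncomplicated, 10\% complicated
#' with oral treatment and 10\% complicated with intravenous treatment.
#'
#' Cohort mass is continuous (an expected-value cohort, matching Markov
#' cohort semantics): 17 192 males aged 16-64 yield a complicated-IV mass of
#' 1719.2, reported as 1719 when an integer view is requested.
#'
#' @param total Total cohort size (non-negative; may be 1 for per-patient
#'   analyses).
#' @param age_sex_weights Named proportions for the four sex-age groups
#'   (names `"F.16-64"`, `"M.16-64"`, `"F.65-100"`, `"M.65-100"`), summing
#'   to 1. Defaults to the packaged weights.
#' @param complicated_split Length-3 proportions
#'   (uncomplicated, complicated-oral, complicated-IV) summing to 1.
#' @return A `cohort_table`: the [uti_strata()] frame plus a continuous
#'   `count` column.
#' @examples
#' ch <- build_cohort(280462)
#' sum(ch$count)
#' @export
build_cohort <- function(total = NULL,
                         age_sex_weights = NULL,
                         complicated_split = c(0.8, 0.1, 0.1)) {
  if (is.null(total) || is.null(age_sex_weights)) {
    ps <- default_parameters()
    total <- total %||% ps$total_cohort
    age_sex_weights <- age_sex_weights %||% ps$age_sex_weights
  }
  stopifnot(is.numeric(total), length(total) == 1L)
  if (total < 0) stop("`total` must be non-negative", call. = FALSE)
  if (any(age_sex_weights < 0)) stop("age-sex weights must be non-negative", call. = FALSE)
  if (abs(sum(age_sex_weights) - 1) > 1e-9) {
    stop("age-sex weights must sum to 1", call. = FALSE)
  }
  if (length(complicated_split) != 3L || any(complicated_split < 0) ||
      abs(sum(complicated_split) - 1) > 1e-9) {
    stop("`complicated_split` must be 3 non-negative proportions summing to 1", call. = FALSE)
  }
  strata <- uti_strata()
  group <- paste(strata$sex, strata$age_band, sep = ".")
  missing <- setdiff(unique(group), names(age_sex_weights))
  if (length(missing)) {
    stop("age_sex_weights lacks group(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  split_by_type <- c(
    uncomplicated = complicated_split[1],
    complicated_oral = complicated_split[2],
    complicated_iv = complicated_split[3]
  )
  strata$count <- total * unname(age_sex_weights[group]) *
    unname(split_by_type[strata$uti_type])
  class(strata) <- c("cohort_table", "data.frame")
  strata
}

#' Integer view of cohort counts
#'
#' Continuous stratum masses rounded half-up for reporting.
#'
#' @param cohort A `cohort_table`.
#' @return The cohort with an integer `count` column.
#' @export
cohort_counts_rounded <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  cohort$count <- floor(cohort$count + 0.5)
  cohort
}

#' Read or write a cohort table as CSV
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @return `read_cohort_csv()` returns a validated `cohort_table`;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("age_band", "sex", "uti_type", "count")
  if (!all(needed %in% names(df))) {
    stop("cohort CSV must carry columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(df$count < 0)) stop("cohort counts must be non-negative", call. = FALSE)
  ref <- uti_strata()
  key <- paste(df$sex, df$age_band, df$uti_type, sep = ".")
  if (!setequal(key, ref$stratum) || length(key) != 12L) {
    stop("cohort CSV must contain exactly the 12 sex x age x UTI-type strata", call. = FALSE)
  }
  df$stratum <- key
  df <- df[match(ref$stratum, key), c("age_band", "sex", "uti_type", "stratum", "count")]
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Discharge and death profile from mean length of stay
#'
#' Converts mean lengths of stay into daily discharge probabilities under a
#' constant exit hazard, `1 - exp(-1/LoS)`, and attaches the share of exits
#' that are deaths. Three state classes are profiled: susceptible infection
#' on appropriate therapy, resistant infection on inappropriate therapy
#' (never a shorter stay than susceptible), and bloodstream infection.
#'
#' @param mean_los_days Named numeric vector with entries
#'   `susceptible_appropriate`, `resistant_inappropriate`, `bsi`; all
#'   strictly positive days.
#' @param mortality_fraction Share of exits that are deaths: a single value
#'   applied to every class, or a named vector matching `mean_los_days`.
#' @return An `exit_profile` `data.frame` with columns `state_class`,
#'   `mean_los_days`, `daily_discharge_prob`, `death_fraction`.
#' @examples
#' exit_profile_from_los(
#'   c(susceptible_appropriate = 5, resistant_inappropriate = 6.5, bsi = 12),
#'   mortality_fraction = c(susceptible_appropriate = 0.028,
#'                          resistant_inappropriate = 0.056, bsi = 0.15)
#' )
#' @export
exit_profile_from_los <- function(mean_los_days, mortality_fraction) {
  classes <- c("susceptible_appropriate", "resistant_inappropriate", "bsi")
  if (!all(classes %in% names(mean_los_days))) {
    stop("`mean_los_days` must name classes: ", paste(classes, collapse = ", "), call. = FALSE)
  }
  los <- mean_los_days[classes]
  if (any(!is.finite(los)) || any(los <= 0)) {
    stop("mean lengths of stay must be positive and finite", call. = FALSE)
  }
  if (length(mortality_fraction) == 1L) {
    mf <- stats::setNames(rep(mortality_fraction, 3L), classes)
  } else {
    if (!all(classes %in% names(mortality_fraction))) {
      stop("named `mortality_fraction` must cover all state classes", call. = FALSE)
    }
    mf <- mortality_fraction[classes]
  }
  if (any(mf < 0) || any(mf > 1)) {
    stop("mortality fractions must lie in [0, 1]", call. = FALSE)
  }
  if (los[["resistant_inappropriate"]] < los[["susceptible_appropriate"]]) {
    stop("resistant-inappropriate mean LoS must not be shorter than susceptible-appropriate",
         call. = FALSE)
  }
  out <- data.frame(
    state_class = classes,
    mean_los_days = unname(los),
    daily_discharge_prob = unname(-expm1(-1 / los)),
    death_fraction = unname(mf),
    stringsAsFactors = FALSE
  )
  class(out) <- c("exit_profile", "data.frame")
  out
}

# Exit profile implied by a parameter set: resistant LoS and death fraction
# are expressed as ratios on the susceptible values so the longer-stay /
# higher-mortality assumptions survive any sampled draw.
#' Exit profile implied by a parameter set
#'
#' @param ps A `parameter_set`.
#' @return An `exit_profile`, see [exit_profile_from_los()].
#' @export
exit_profile_from_params <- function(ps) {
  stopifnot(inherits(ps, "parameter_set"))
  exit_profile_from_los(
    mean_los_days = c(
      susceptible_appropriate = ps$mean_los_uti_days,
      resistant_inappropriate = ps$mean_los_uti_days * ps$los_ratio_resistant,
      bsi = ps$mean_los_bsi_days
    ),
    mortality_fraction = c(
      susceptible_appropriate = ps$mortality_fraction_uti,
      resistant_inappropriate = min(1, ps$mortality_fraction_uti * ps$mortality_ratio_resistant),
      bsi = ps$mortality_fraction_bsi
    )
  )
}

#' Prevalence of resistant infection under inappropriate empirical therapy
#'
#' The model's entry split: a patient starts in the inappropriate-treatment
#' state when the pathogen is resistant to the empirical antibiotic and the
#' prescribing was inappropriate; the joint prevalence is the product of the
#' two proportions (independence assumed).
#'
#' @param resistance_prev Prevalence of resistance to the empirical
#'   antibiotic, in `[0, 1]`.
#' @param inappropriate_prop Share of prescribing that is inappropriate,
#'   in `[0, 1]`.
#' @return The joint proportion.
#' @examples
#' resistant_inappropriate_prevalence(0.05, 0.20)
#' @export
resistant_inappropriate_prevalence <- function(resistance_prev, inappropriate_prop) {
  if (any(resistance_prev < 0) || any(resistance_prev > 1) ||
      any(inappropriate_prop < 0) || any(inappropriate_prop > 1)) {
    stop("both proportions must lie in [0, 1]", call. = FALSE)
  }
  resistance_prev * inappropriate_prop
}
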