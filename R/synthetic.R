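# Representative 4-character codes used when emitting microdata for a true
# target cause; each sits squarely inside its subgroup's code range.
.target_code <- c(
  TRANSPORT_INJURY = "V031",
  FALLS            = "W109",
  SUICIDE          = "X700",
  HOMICIDE         = "X954",
  OTHER_TRANSPORT  = "V905",
  OTHER_EXTERNAL   = "X099"
)

#' Standard age bins
#'
#' The conventional vital-statistics bins: under 1, 1-4, then 5-year bins to
#' 80-84, and 85+.
#'
#' @return Character vector of 19 age-group labels.
#' @export
default_age_bins <- function() {
  c("0", "1-4", paste(seq(5, 80, 5), seq(9, 84, 5), sep = "-"), "85+")
}

# Plausible adult-skewed distribution of external-cause deaths over the bins:
# mass concentrated in 15-49, a tail into old age (falls).
.default_age_probs <- function() {
  p <- c(0.5, 0.5, 0.5, 1, 4, 8, 9, 9, 8, 7, 6, 5, 4.5, 4, 3.5, 3, 3, 3, 4)
  p / sum(p)
}

#' Scenario configuration for the synthetic microdata generator
#'
#' Defines the study conditions a simulated registry emulates: stratum sizes,
#' the true cause mixture over the six external target subgroups, how garbage
#' contamination arises (a true cause's code is overwritten by a garbage
#' code), missingness of sex/age, and under-registration (records are thinned
#' so that true deaths exceed registered ones by the given factor).
#'
#' `garbage_fraction` may be a single probability (cause-independent
#' relabeling, under which proportional redistribution is unbiased) or a named
#' vector per cause (cause-conditional relabeling, the failure mode that
#' motivates the investigated-death criterion).
#'
#' @param ufs Units simulated; default all 27.
#' @param years Calendar years; default 2015.
#' @param n_per_stratum Expected deaths per (uf, year) stratum; default 2000.
#' @param cause_mix Named probabilities over [external_targets()], summing
#'   to 1.
#' @param garbage_fraction Scalar or named-per-cause relabeling probability,
#'   default 0.2.
#' @param garbage_palette Garbage codes used for relabeling (uniformly);
#'   defaults to four proportional-class codes.
#' @param p_missing_sex,p_missing_age Masking probabilities, default 0.
#' @param underregistration_factor True/registered ratio >= 1 used to thin
#'   records, default 1 (complete registration).
#' @param age_probs Probabilities over [default_age_bins()].
#' @param pop_per_cell Person-years per (uf, year, sex, age bin) population
#'   cell, default 50000.
#' @return A validated list of class `gc_scenario`.
#' @export
scenario_config <- function(ufs = uf_codes(),
                            years = 2015,
                            n_per_stratum = 2000,
                            cause_mix = c(
                              TRANSPORT_INJURY = 0.25, FALLS = 0.12,
                              SUICIDE = 0.10, HOMICIDE = 0.35,
                              OTHER_TRANSPORT = 0.05, OTHER_EXTERNAL = 0.13
                            ),
                            garbage_fraction = 0.2,
                            garbage_palette = c("Y872", "X449", "Y259", "W619"),
                            p_missing_sex = 0,
                            p_missing_age = 0,
                            underregistration_factor = 1,
                            age_probs = .default_age_probs(),
                            pop_per_cell = 50000) {
  if (!setequal(names(cause_mix), external_targets())) {
    stop("cause_mix must be named over the six external targets", call. = FALSE)
  }
  if (all(cause_mix == 0)) stop("degenerate cause mixture: all zero", call. = FALSE)
  if (abs(sum(cause_mix) - 1) > 1e-9) stop("cause_mix must sum to 1", call. = FALSE)
  if ((length(garbage_fraction) > 1 || !is.null(names(garbage_fraction))) &&
      !setequal(names(garbage_fraction), external_targets())) {
    stop("per-cause garbage_fraction must be named over the six external targets",
         call. = FALSE)
  }
  if (any(garbage_fraction < 0 | garbage_fraction >= 1)) {
    stop("garbage_fraction must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(
    n_per_stratum > 0, underregistration_factor >= 1,
    p_missing_sex >= 0, p_missing_sex <= 1,
    p_missing_age >= 0, p_missing_age <= 1,
    length(age_probs) == length(default_age_bins()),
    abs(sum(age_probs) - 1) < 1e-9
  )
  structure(
    list(
      ufs = ufs, years = as.integer(years), n_per_stratum = n_per_stratum,
      cause_mix = cause_mix[external_targets()],
      garbage_fraction = garbage_fraction,
      garbage_palette = garbage_palette,
      p_missing_sex = p_missing_sex, p_missing_age = p_missing_age,
      underregistration_factor = underregistration_factor,
      age_probs = age_probs, pop_per_cell = pop_per_cell
    ),
    class = "gc_scenario"
  )
}

#' Generate synthetic registry microdata with known truth
#'
#' Draws `n_per_stratum` deaths for every (uf, year) stratum: a true cause
#' from the mixture, sex (balanced), an age bin; then, with the configured
#' per-cause probability, overwrites the cause code with a garbage code drawn
#' uniformly from the palette. Sex/age are masked to `NA` with the configured
#' probabilities and records are thinned by the under-registration factor.
#' The truth table records true-cause totals per stratum before masking and
#' thinning. Byte-identical output for the same seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer RNG seed (optional).
#' @return List with `records` (microdata tibble: `year`, `uf`, `sex`,
#'   `age_group`, `cause`, `weight`), `truth` (true deaths per uf/year/
#'   cause), and `population` (uf/year/sex/age_group person-years).
#' @export
simulate_deaths <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gc_scenario"))
  if (!is.null(seed)) set.seed(seed)
  strata <- expand.grid(uf = config$ufs, year = config$years,
                        stringsAsFactors = FALSE)
  n <- config$n_per_stratum
  total <- nrow(strata) * n
  targets <- external_targets()

  df <- tibble::tibble(
    uf = rep(strata$uf, each = n),
    year = rep(strata$year, each = n),
    sex = sample(c("male", "female"), total, replace = TRUE),
    age_group = sample(default_age_bins(), total, replace = TRUE,
                       prob = config$age_probs),
    true_cause = sample(targets, total, replace = TRUE,
                        prob = as.numeric(config$cause_mix))
  )
  g <- config$garbage_fraction
  p_garbage <- if (length(g) == 1) rep(g, total) else as.numeric(g[df$true_cause])
  relabel <- stats::runif(total) < p_garbage
  df$cause <- unname(.target_code[df$true_cause])
  if (any(relabel)) {
    df$cause[relabel] <- sample(config$garbage_palette, sum(relabel), replace = TRUE)
  }

  truth <- df |>
    dplyr::count(.data$uf, .data$year, .data$true_cause, name = "deaths") |>
    dplyr::rename(cause_category = "true_cause")

  if (config$p_missing_sex > 0) {
    df$sex[stats::runif(total) < config$p_missing_sex] <- NA_character_
  }
  if (config$p_missing_age > 0) {
    df$age_group[stats::runif(total) < config$p_missing_age] <- NA_character_
  }
  if (config$underregistration_factor > 1) {
    df <- df[stats::runif(nrow(df)) < 1 / config$underregistration_factor, , drop = FALSE]
  }

  population <- tidyr::expand_grid(
    uf = config$ufs, year = config$years,
    sex = c("male", "female"), age_group = default_age_bins()
  )
  population$pop <- config$pop_per_cell

  records <- tibble::as_tibble(df[c("year", "uf", "sex", "age_group", "cause")])
  records$weight <- 1
  list(records = records, truth = tibble::as_tibble(truth),
       population = population)
}

#' True reclassification fractions implied by a scenario
#'
#' Under the generator's relabeling model the fraction of garbage deaths whose
#' true cause is `c` equals `g_c * mix_c / sum_k g_k * mix_k` (Bayes), the
#' same for every palette code since the palette draw does not depend on the
#' cause. Feeding these fractions to [investigation_weights()] makes
#' redistribution unbiased even under cause-conditional relabeling.
#'
#' @param config A [scenario_config()].
#' @return A [read_reclass_table()]-compatible tibble with one row set per
#'   palette code.
#' @export
true_reclass_fractions <- function(config) {
  stopifnot(inherits(config, "gc_scenario"))
  g <- config$garbage_fraction
  targets <- external_targets()
  if (length(g) == 1) g <- setNames(rep(g, length(targets)), targets)
  post <- g[targets] * config$cause_mix[targets]
  post <- post / sum(post)
  read_reclass_table(tidyr::expand_grid(
    garbage = unique(substr(config$garbage_palette, 1L, 3L)),
    tibble::tibble(destination = targets, fraction = as.numeric(post))
  ))
}
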