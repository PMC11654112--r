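# The 27 federative units (26 states + Federal District), two-letter codes.
.uf_codes <- c(
  "AC", "AL", "AM", "AP", "BA", "CE", "DF", "ES", "GO", "MA", "MG", "MS",
  "MT", "PA", "PB", "PE", "PI", "PR", "RJ", "RN", "RO", "RR", "RS", "SC",
  "SE", "SP", "TO"
)

#' Federative-unit codes
#' @return Character vector of the 27 two-letter UF codes.
#' @export
uf_codes <- function() .uf_codes

#' Round half away from zero
#'
#' Reporting convention for rate tables (R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Directly age-standardized rate per 100,000
#'
#' Computes `sum_a (d_a / n_a) * w_a * 1e5` with `w_a = standard_a /
#' sum(standard)`: each age bin's death rate weighted by the standard
#' population's age structure. The result is invariant to proportional
#' scaling of the standard.
#'
#' @param deaths,population,standard Numeric vectors over the same age bins;
#'   if named, names must agree (bins are aligned by name).
#' @return The standardized rate per 100,000 person-years.
#' @examples
#' direct_standardized_rate(c(5, 30), c(50000, 100000), c(60, 40))
#' @export
direct_standardized_rate <- function(deaths, population, standard) {
  if (!is.null(names(deaths)) && !is.null(names(population))) {
    if (!setequal(names(deaths), names(population)) ||
        !setequal(names(deaths), names(standard))) {
      stop("age-bin mismatch: deaths [", paste(names(deaths), collapse = ","),
           "] vs population [", paste(names(population), collapse = ","),
           "] vs standard [", paste(names(standard), collapse = ","), "]",
           call. = FALSE)
    }
    population <- population[names(deaths)]
    standard <- standard[names(deaths)]
  }
  if (length(deaths) != length(population) || length(deaths) != length(standard)) {
    stop("deaths, population and standard must cover the same age bins", call. = FALSE)
  }
  if (any(population <= 0)) stop("population counts must be strictly positive", call. = FALSE)
  w <- standard / sum(standard)
  sum(deaths / population * w) * 1e5
}

#' Percent variation between two rates
#'
#' @param rate_start,rate_end Rates at the start and end of the period.
#' @return `100 * (rate_end - rate_start) / rate_start`, `NA` (with a
#'   warning) where `rate_start` is zero. Unrounded; report with
#'   [round_half_up()] at one decimal.
#' @examples
#' percent_variation(66.5, 57.8)
#' @export
percent_variation <- function(rate_start, rate_end) {
  out <- 100 * (rate_end - rate_start) / rate_start
  zero <- rate_start == 0
  if (any(zero, na.rm = TRUE)) {
    warning("percent variation undefined where the starting rate is zero")
    out[zero] <- NA_real_
  }
  out
}

#' Rate-ratio correction factor
#'
#' The method's summary correction factor: the corrected standardized rate
#' divided by the registered (uncorrected) one.
#'
#' @param rate_corrected,rate_registered Standardized rates.
#' @return `rate_corrected / rate_registered`, `NA` (with a warning) where the
#'   registered rate is zero. Unrounded; report at two decimals.
#' @examples
#' correction_ratio(75.6, 66.5)
#' @export
correction_ratio <- function(rate_corrected, rate_registered) {
  out <- rate_corrected / rate_registered
  zero <- rate_registered == 0
  if (any(zero, na.rm = TRUE)) {
    warning("correction ratio undefined where the registered rate is zero")
    out[zero] <- NA_real_
  }
  out
}

#' Loess-smoothed trend of a rate series
#'
#' Locally weighted polynomial regression (tricube weights, no robustness
#' iterations) evaluated at the observed years. Deterministic given inputs.
#'
#' @param year,rate Numeric vectors of equal length (>= degree + 2 points).
#' @param span Smoothing parameter in (0, 1]; default 0.75.
#' @param degree Local polynomial degree, 1 (default) or 2.
#' @return Tibble with columns `year`, `rate`, `smoothed`.
#' @export
loess_trend <- function(year, rate, span = 0.75, degree = 1) {
  if (length(year) != length(rate)) stop("year and rate lengths differ", call. = FALSE)
  if (length(year) < degree + 2) {
    stop("loess needs at least degree + 2 = ", degree + 2, " points", call. = FALSE)
  }
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]", call. = FALSE)
  fit <- stats::loess(
    rate ~ year,
    data = data.frame(year = year, rate = rate),
    span = span, degree = degree, family = "gaussian",
    control = stats::loess.control(surface = "direct")
  )
  tibble::tibble(year = year, rate = rate,
                 smoothed = as.numeric(stats::predict(fit, newdata = data.frame(year = year))))
}

#' Rank federative units by standardized rate
#'
#' Descending by rate, ties broken alphabetically by UF code. When a second
#' method's rates are supplied, also reports each unit's rank under it and the
#' rank delta (positive = the unit rises under the comparison method); deltas
#' sum to zero.
#'
#' @param rates Tibble with columns `uf` and `rate`, one row per unit.
#' @param rates_compare Optional second tibble with the same shape.
#' @param ufs The required set of units; defaults to the 27 federative units.
#' @return Tibble with `uf`, `rate`, `rank` (plus `rate_compare`,
#'   `rank_compare`, `delta` when comparing), ordered by `rank`.
#' @export
rank_ufs <- function(rates, rates_compare = NULL, ufs = uf_codes()) {
  .check_ranking_input <- function(x, label) {
    x <- tibble::as_tibble(x)
    missing <- setdiff(ufs, x$uf)
    if (length(missing)) {
      stop(label, " is missing units: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    dup <- x$uf[duplicated(x$uf)]
    if (length(dup)) stop(label, " has duplicate units: ", paste(dup, collapse = ", "), call. = FALSE)
    x[x$uf %in% ufs, c("uf", "rate")]
  }
  a <- .check_ranking_input(rates, "rates")
  a <- a[order(-a$rate, a$uf), ]
  a$rank <- seq_len(nrow(a))
  if (is.null(rates_compare)) return(a)
  b <- .check_ranking_input(rates_compare, "rates_compare")
  b <- b[order(-b$rate, b$uf), ]
  b$rank <- seq_len(nrow(b))
  names(b) <- c("uf", "rate_compare", "rank_compare")
  out <- dplyr::left_join(a, b, by = "uf")
  out$delta <- out$rank - out$rank_compare
  out
}

#' Age-standardized rate table from weighted records
#'
#' Aggregates redistributed death records and a population table into directly
#' standardized rates per 100,000 for each group (by default state x year).
#' Standardization is by age only: deaths and person-years are collapsed over
#' sex within each age bin. The standard is the `standard_year` age structure
#' of the whole population.
#'
#' @param records Records with `age_group` and `weight` plus grouping columns.
#' @param population Tibble with `uf`, `year`, `sex`, `age_group`, `pop`.
#' @param by Grouping columns, default `c("uf", "year")`; use `"year"` for
#'   national rates.
#' @param standard_year Year whose national age structure is the standard;
#'   `NULL` (default) uses the earliest year in the population table (the
#'   study convention is the first year of the series, 2010).
#' @return Tibble with `by` columns and `rate`.
#' @export
standardized_rates <- function(records, population, by = c("uf", "year"),
                               standard_year = NULL) {
  records <- tibble::as_tibble(records)
  population <- tibble::as_tibble(population)
  if (is.null(standard_year)) standard_year <- min(population$year)
  standard <- population |>
    dplyr::filter(.data$year == standard_year) |>
    dplyr::group_by(.data$age_group) |>
    dplyr::summarise(std = sum(.data$pop), .groups = "drop")
  if (nrow(standard) == 0) {
    stop("population table has no rows for standard year ", standard_year, call. = FALSE)
  }
  # grouping columns absent from the population table (e.g. cause category)
  # share their group's population denominators
  by_pop <- intersect(by, names(population))
  pop_by <- population |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by_pop, "age_group")))) |>
    dplyr::summarise(pop = sum(.data$pop), .groups = "drop")
  deaths_by <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "age_group")))) |>
    dplyr::summarise(deaths = sum(.data$weight), .groups = "drop")
  groups <- dplyr::distinct(records[by])
  cells <- if (length(by_pop)) {
    dplyr::inner_join(groups, pop_by, by = by_pop, relationship = "many-to-many")
  } else {
    dplyr::cross_join(groups, pop_by)
  }
  full <- dplyr::left_join(cells, deaths_by, by = c(by, "age_group")) |>
    dplyr::mutate(deaths = dplyr::coalesce(.data$deaths, 0))
  orphans <- dplyr::anti_join(deaths_by, pop_by, by = c(by_pop, "age_group"))
  if (nrow(orphans) > 0) {
    stop("age bins with deaths but no population: ",
         paste(utils::head(orphans$age_group, 5), collapse = ", "), call. = FALSE)
  }
  full <- dplyr::left_join(full, standard, by = "age_group")
  if (anyNA(full$std)) {
    stop("standard population does not cover age bins: ",
         paste(unique(full$age_group[is.na(full$std)]), collapse = ", "),
         call. = FALSE)
  }
  full |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      rate = direct_standardized_rate(.data$deaths, .data$pop, .data$std),
      .groups = "drop"
    )
}
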