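#' Read registry-style microdata
#'
#' Expects the package's plain CSV dialect: `year`, `uf`, `sex` (coded `1` =
#' male, `2` = female, blank = missing), `age` in years (blank = missing),
#' `cause` (free-text ICD-10), optional `munic`. A `dialect` mapping renames
#' registry-specific headers (e.g. the DO fields `DTOBITO`, `SEXO`, `IDADE`,
#' `CAUSABAS`, `CODMUNRES`) onto this schema before parsing.
#'
#' @param path CSV path.
#' @param dialect Optional named character vector `c(internal = "external")`
#'   renaming columns.
#' @param age_bins Cut points are derived from [default_age_bins()].
#' @return Tibble with `year`, `uf`, `sex`, `age_group`, `cause`, `weight`.
#' @export
read_microdata <- function(path, dialect = NULL, age_bins = default_age_bins()) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(dialect)) {
    for (internal in names(dialect)) {
      if (dialect[[internal]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[internal]]] <- internal
      }
    }
  }
  required <- c("year", "uf", "sex", "age", "cause")
  miss <- setdiff(required, names(raw))
  if (length(miss)) stop("microdata missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  sex <- dplyr::case_match(raw$sex, "1" ~ "male", "2" ~ "female",
                           "male" ~ "male", "female" ~ "female",
                           .default = NA_character_)
  tibble::tibble(
    year = as.integer(raw$year),
    uf = raw$uf,
    sex = sex,
    age_group = age_to_bin(suppressWarnings(as.numeric(raw$age)), age_bins),
    cause = normalize_icd10(raw$cause),
    weight = 1
  )
}

#' Assign ages in years to age bins
#'
#' @param age Numeric ages (NA allowed).
#' @param age_bins Labels as produced by [default_age_bins()].
#' @return Character bin labels (NA preserved).
#' @export
age_to_bin <- function(age, age_bins = default_age_bins()) {
  lower <- c(0, 1, seq(5, 85, 5))
  idx <- findInterval(age, lower)
  out <- age_bins[idx]
  out[is.na(age) | age < 0] <- NA_character_
  out
}

#' Read a population table
#'
#' @param path CSV with columns `uf`, `year`, `sex`, `age_group`, `pop`.
#' @return Validated tibble.
#' @export
read_population <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), pop = readr::col_double(),
    .default = readr::col_character()
  ))
  required <- c("uf", "year", "sex", "age_group", "pop")
  miss <- setdiff(required, names(tbl))
  if (length(miss)) stop("population table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(tbl$pop <= 0)) stop("population counts must be strictly positive", call. = FALSE)
  tbl
}

#' Run the full correction pipeline on one variant
#'
#' Stages, in order: cause mapping, universe rules, proportional
#' redistribution of missing demographics, garbage-code redistribution,
#' under-registration correction (gbd_brasil only), then age-standardized
#' rates. A conservation audit logs total weight after every stage: totals are
#' constant from the universe partition until the correction stage, the only
#' stage allowed to change mass.
#'
#' @param records Microdata tibble (see [read_microdata()]) or a
#'   [simulate_deaths()] `records` element.
#' @param population Population tibble.
#' @param variant `"gbd_brasil"` (default) or `"direct_sim"` (registered
#'   data: X59/Y34 and natural classes excluded, proportional criterion only,
#'   no under-registration correction).
#' @param map Cause map; default [build_cause_map()].
#' @param reclass Reclassification table (required for `"gbd_brasil"` when
#'   investigation classes are present).
#' @param factors Optional correction factors (gbd_brasil only).
#' @param standard_year Standard-population year for rates; default the earliest year.
#' @param rate_by Grouping for the rate table, default `c("uf", "year")`.
#' @return List of class `gc_pipeline` with `records` (final weighted
#'   records), `rates`, `rates_by_cause`, `audit` (stage/total-weight log) and
#'   `variant`.
#' @export
run_pipeline <- function(records, population,
                         variant = c("gbd_brasil", "direct_sim"),
                         map = build_cause_map(), reclass = NULL,
                         factors = NULL, standard_year = NULL,
                         rate_by = c("uf", "year")) {
  variant <- match.arg(variant)
  audit <- list()
  note <- function(stage, df) {
    audit[[length(audit) + 1]] <<- tibble::tibble(stage = stage, total_weight = sum(df$weight))
  }

  records <- ensure_category(records, map)
  note("input", records)

  parts <- apply_sim_universe(records, map, variant)
  ext <- parts$external
  note("universe", ext)

  ext <- redistribute_missing(ext, fields = c("sex", "age_group", "year"))
  note("missing_redistributed", ext)

  policy <- default_redistribution_policy()
  if (variant == "direct_sim") {
    policy$criterion[] <- "proportional"
    policy$destinations <- lapply(policy$destinations, function(x) external_targets())
  }
  ext <- redistribute_garbage(ext, map, reclass = reclass, policy = policy)
  note("garbage_redistributed", ext)

  if (variant == "gbd_brasil" && !is.null(factors)) {
    ext <- apply_underregistration(ext, factors)
    note("underregistration_corrected", ext)
  }

  final <- ext[ext$cause_category %in% .target_categories, , drop = FALSE]
  rates <- standardized_rates(final[final$cause_category %in% external_targets(), ],
                              population, by = rate_by, standard_year = standard_year)
  rates_by_cause <- standardized_rates(
    final[final$cause_category %in% external_targets(), ],
    population, by = c(rate_by, "cause_category"), standard_year = standard_year
  )

  structure(
    list(records = ext, rates = rates, rates_by_cause = rates_by_cause,
         audit = dplyr::bind_rows(audit), variant = variant),
    class = "gc_pipeline"
  )
}

#' @export
print.gc_pipeline <- function(x, ...) {
  cat("<gc_pipeline>", x$variant, "variant\n")
  print(x$audit)
  invisible(x)
}

#' Compare the corrected and registered arms
#'
#' Runs both pipeline variants on the same microdata and assembles the
#' comparison tables the method reports: standardized rates per unit and year
#' under each arm, percent variation between the first and last year, the
#' rate-ratio correction factor `r = corrected / registered`, and the
#' end-year ranking with rank deltas.
#'
#' @inheritParams run_pipeline
#' @param ufs Units expected in the ranking; defaults to the units present.
#' @return List with `rates` (method x uf x year), `variation`, `ratios`,
#'   `ranking`, and the two `gc_pipeline` bundles.
#' @export
compare_methods <- function(records, population, map = build_cause_map(),
                            reclass = NULL, factors = NULL,
                            standard_year = NULL, ufs = NULL) {
  corrected <- run_pipeline(records, population, "gbd_brasil", map = map,
                            reclass = reclass, factors = factors,
                            standard_year = standard_year)
  registered <- run_pipeline(records, population, "direct_sim", map = map,
                             standard_year = standard_year)
  rates <- dplyr::bind_rows(
    dplyr::mutate(corrected$rates, method = "gbd_brasil"),
    dplyr::mutate(registered$rates, method = "direct_sim")
  )
  y0 <- min(rates$year); y1 <- max(rates$year)
  wide <- rates |>
    tidyr::pivot_wider(names_from = "year", values_from = "rate",
                       names_prefix = "rate_")
  variation <- if (y1 > y0) {
    dplyr::mutate(wide, variation = percent_variation(
      .data[[paste0("rate_", y0)]], .data[[paste0("rate_", y1)]]
    ))
  } else wide
  ratios <- rates |>
    tidyr::pivot_wider(names_from = "method", values_from = "rate") |>
    dplyr::mutate(ratio = correction_ratio(.data$gbd_brasil, .data$direct_sim))
  if (is.null(ufs)) ufs <- sort(unique(rates$uf))
  last_corrected <- dplyr::filter(corrected$rates, .data$year == y1)
  last_registered <- dplyr::filter(registered$rates, .data$year == y1)
  ranking <- rank_ufs(last_corrected, last_registered, ufs = ufs)
  list(rates = rates, variation = variation, ratios = ratios,
       ranking = ranking, corrected = corrected, registered = registered)
}

#' Write the comparison bundle to CSV files
#'
#' @param bundle A [compare_methods()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    rates = file.path(dir, "rates.csv"),
    variation = file.path(dir, "variation.csv"),
    ratios = file.path(dir, "ratios.csv"),
    ranking = file.path(dir, "ranking.csv"),
    audit = file.path(dir, "audit.csv")
  )
  readr::write_csv(bundle$rates, paths[["rates"]])
  readr::write_csv(bundle$variation, paths[["variation"]])
  readr::write_csv(bundle$ratios, paths[["ratios"]])
  readr::write_csv(bundle$ranking, paths[["ranking"]])
  readr::write_csv(dplyr::bind_rows(
    dplyr::mutate(bundle$corrected$audit, variant = "gbd_brasil"),
    dplyr::mutate(bundle$registered$audit, variant = "direct_sim")
  ), paths[["audit"]])
  invisible(paths)
}
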