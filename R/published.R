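#' Published comparison tables
#'
#' Loads the study's published summary tables shipped with the package:
#' `published_rates()` returns the 2010/2019 age-standardized external-cause
#' mortality rates per 100,000 for Brazil and the 27 federative units under
#' the three methods (registered SIM data, GBD-IHME estimates, GBD-Brasil
#' correction) together with the printed percent variations;
#' `published_ratios()` returns the printed rate-ratio correction factors
#' (corrected / registered) by cause group. These printed values serve as
#' worked-example inputs for the arithmetic operations
#' ([percent_variation()], [correction_ratio()], [rank_ufs()]).
#'
#' @return A tibble; `uf` is the two-letter unit code (`"BR"` for the national
#'   row).
#' @export
published_rates <- function() {
  readr::read_csv(
    system.file("extdata", "published_rates_2010_2019.csv", package = "gcredist"),
    col_types = readr::cols(
      region = readr::col_character(), uf = readr::col_character(),
      name = readr::col_character(), .default = readr::col_double()
    )
  )
}

#' @rdname published_rates
#' @export
published_ratios <- function() {
  readr::read_csv(
    system.file("extdata", "published_correction_ratios.csv", package = "gcredist"),
    col_types = readr::cols(
      region = readr::col_character(), uf = readr::col_character(),
      name = readr::col_character(), .default = readr::col_double()
    )
  )
}
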