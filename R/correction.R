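#' Read under-registration correction factors
#'
#' @param x Path to a CSV with columns `uf`, `sex`, `age_group`, optional
#'   `year`, and `factor`, or a data frame with those columns. Factors must be
#'   >= 1: under-registration only inflates counts.
#' @return A validated tibble of class `correction_factors`.
#' @export
read_correction_factors <- function(x) {
  tbl <- if (is.character(x)) {
    out <- readr::read_csv(x, col_types = readr::cols(
      factor = readr::col_double(), .default = readr::col_character()
    ))
    if ("year" %in% names(out)) out$year <- as.integer(out$year)
    out
  } else {
    tibble::as_tibble(x)
  }
  if (!"factor" %in% names(tbl)) {
    stop("correction-factor table needs a 'factor' column", call. = FALSE)
  }
  if (any(tbl$factor < 1)) {
    stop("under-registration factors must be >= 1; offending rows: ",
         paste(which(tbl$factor < 1), collapse = ", "), call. = FALSE)
  }
  class(tbl) <- c("correction_factors", class(tbl))
  tbl
}

#' Apply under-registration correction factors
#'
#' Multiplies each record's weight by the factor of its (state, sex, age
#' group, optionally year) stratum. This is the last pipeline stage: it must
#' run after redistribution, since the redistribution weights are computed on
#' registered (uncorrected) counts.
#'
#' @param records Redistributed records with a `weight` column.
#' @param factors A [read_correction_factors()] table.
#' @param default_factor Factor used for strata absent from the table; `NULL`
#'   (default) makes a missing stratum an error.
#' @return Records with inflated weights.
#' @export
apply_underregistration <- function(records, factors, default_factor = NULL) {
  records <- tibble::as_tibble(records)
  factors <- read_correction_factors(factors)
  keys <- intersect(intersect(c("uf", "sex", "age_group", "year"), names(factors)),
                    names(records))
  if (!length(keys)) stop("no stratum columns shared between records and factors", call. = FALSE)
  joined <- dplyr::left_join(records, factors[c(keys, "factor")], by = keys)
  if (nrow(joined) != nrow(records)) {
    stop("correction-factor table has duplicate rows for some strata", call. = FALSE)
  }
  miss <- is.na(joined$factor)
  if (any(miss)) {
    if (is.null(default_factor)) {
      ex <- joined[which(miss)[1], keys, drop = FALSE]
      stop("no correction factor for stratum ",
           paste(names(ex), unlist(ex), sep = "=", collapse = ", "),
           " and no default given", call. = FALSE)
    }
    joined$factor[miss] <- default_factor
  }
  joined$weight <- joined$weight * joined$factor
  joined$factor <- NULL
  joined
}
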