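#' Apply the external-cause universe rules
#'
#' Partitions classified death records into the external-cause universe and an
#' excluded remainder. The universe always contains the six external target
#' subgroups and the proportionally-redistributed external garbage (including
#' the natural codes that the method treats as external: the L55/L56/L58
#' radiation-injury group as targets and G443/G913/R58 as garbage). Codes
#' reclassified as chronic-disease poisonings and neonatal pulmonary
#' aspiration are always excluded, as is anything outside the study universe.
#'
#' Under the `"direct_sim"` variant the unspecified-exposure and
#' undetermined-intent garbage (X59/Y34), the pneumonia class and the natural
#' garbage classes are also excluded, so the registered-data arm counts only
#' external causes and their within-universe garbage. Under `"gbd_brasil"`
#' those classes stay in the universe and are redistributed downstream.
#'
#' @param records A tibble of death records with columns `cause` (canonical
#'   ICD-10) and `weight`; a `cause_category` column is added if absent.
#' @param map A [build_cause_map()] object.
#' @param variant `"gbd_brasil"` (default) or `"direct_sim"`.
#' @return A list with tibbles `external` and `excluded`; total weight is
#'   conserved across the partition.
#' @export
apply_sim_universe <- function(records, map, variant = c("gbd_brasil", "direct_sim")) {
  variant <- match.arg(variant)
  records <- ensure_category(records, map)
  excluded_cats <- c(.excluded_categories, "OUT_OF_UNIVERSE")
  if (variant == "direct_sim") {
    excluded_cats <- c(excluded_cats, "GC_INVESTIGATION", "GC_NATURAL", "PNEUMONIA_TARGET")
  }
  keep <- !(records$cause_category %in% excluded_cats)
  list(
    external = records[keep, , drop = FALSE],
    excluded = records[!keep, , drop = FALSE]
  )
}

# Add cause_category from the map when the caller has not classified yet.
ensure_category <- function(records, map = NULL) {
  records <- tibble::as_tibble(records)
  if (!"weight" %in% names(records)) records$weight <- 1
  if (!"cause_category" %in% names(records)) {
    if (is.null(map)) stop("records lack a cause_category column and no map was given", call. = FALSE)
    records$cause_category <- classify_icd10(normalize_icd10(records$cause), map)
  }
  records
}

# Fallback chain for a field: narrowest stratum first, then successively
# coarser by dropping municipality, then state, then cause category, then
# everything (national all-cause pool). Year never enters its own chain.
.fallback_chain <- function(field, cols, condition_on_cause) {
  keys <- intersect(c("municipality", "uf", "year", "cause_category"), cols)
  if (!condition_on_cause) keys <- setdiff(keys, "cause_category")
  keys <- setdiff(keys, field)
  drop_order <- intersect(c("municipality", "uf", "cause_category", "year"), keys)
  chain <- list(keys)
  for (d in drop_order) {
    keys <- setdiff(keys, d)
    chain <- c(chain, list(keys))
  }
  chain
}

#' Proportionally redistribute records with missing demographics
#'
#' Each record missing one of `fields` is replaced by fractional-weight copies
#' spread over the observed (weight-weighted) distribution of that field among
#' complete records in the narrowest non-empty stratum. The default stratum is
#' (municipality if present, state, year, cause category), coarsened stepwise
#' until a non-empty pool is found; conditioning on cause category keeps
#' garbage deaths from borrowing the demographic structure of unrelated
#' causes and can be switched off.
#'
#' Fields are processed in the order sex, age group, year; records missing
#' several fields are split sequentially on the successive marginal
#' distributions. Total weight is conserved and the operation is idempotent.
#'
#' @param records Tibble with columns `uf`, `year`, `sex`, `age_group`,
#'   `cause_category` (or `cause` plus `map`), `weight`; missing values are
#'   `NA`.
#' @param fields Which fields to complete (subset of `sex`, `age_group`,
#'   `year`).
#' @param map Optional [build_cause_map()] used when `cause_category` is
#'   absent.
#' @param condition_on_cause Include the cause category in the stratum
#'   definition (default `TRUE`).
#' @return Tibble with no missing values in `fields`, same total weight.
#' @export
redistribute_missing <- function(records,
                                 fields = c("sex", "age_group", "year"),
                                 map = NULL,
                                 condition_on_cause = TRUE) {
  fields <- match.arg(fields, several.ok = TRUE)
  records <- if (condition_on_cause) ensure_category(records, map) else {
    x <- tibble::as_tibble(records)
    if (!"weight" %in% names(x)) x$weight <- 1
    x
  }
  order_fields <- intersect(c("sex", "age_group", "year"), fields)
  for (f in order_fields) {
    records <- .impute_one_field(records, f, condition_on_cause)
  }
  records
}

.impute_one_field <- function(records, field, condition_on_cause) {
  miss <- is.na(records[[field]])
  if (!any(miss)) return(records)
  complete <- records[!miss, , drop = FALSE]
  if (nrow(complete) == 0) {
    stop("no complete records available to impute field '", field, "'", call. = FALSE)
  }
  pending <- records[miss, , drop = FALSE]
  pending[[field]] <- NULL

  chain <- .fallback_chain(field, names(records), condition_on_cause)
  pieces <- list(complete)
  for (keys in chain) {
    if (nrow(pending) == 0) break
    dist <- complete |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, field)))) |>
      dplyr::summarise(.pool = sum(.data$weight), .groups = "drop")
    dist <- dist |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::mutate(.share = .data$.pool / sum(.data$.pool)) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(c(keys, field)), ".share")
    if (length(keys)) {
      matched <- dplyr::inner_join(pending, dist, by = keys,
                                   relationship = "many-to-many")
      pending <- dplyr::anti_join(pending, dist, by = keys)
    } else {
      matched <- dplyr::cross_join(pending, dist)
      pending <- pending[0, , drop = FALSE]
    }
    if (nrow(matched)) {
      matched$weight <- matched$weight * matched$.share
      matched$.share <- NULL
      pieces <- c(pieces, list(matched))
    }
  }
  if (nrow(pending) > 0) {
    stop("no complete records at any fallback level to impute '", field,
         "' for stratum: ",
         paste(utils::capture.output(print(utils::head(pending, 1))), collapse = " "),
         call. = FALSE)
  }
  out <- dplyr::bind_rows(pieces)
  out[names(records)]
}
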