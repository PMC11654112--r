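#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

# Cause taxonomy. The first seven labels are the legal redistribution
# destinations ("target causes"); pneumonia is a target because a sizeable
# residual of pneumonia-coded deaths remains pneumonia after investigation.
.target_categories <- c(
  "TRANSPORT_INJURY", "FALLS", "SUICIDE", "HOMICIDE",
  "OTHER_TRANSPORT", "OTHER_EXTERNAL", "PNEUMONIA_TARGET"
)
.garbage_categories <- c("GC_INVESTIGATION", "GC_PROPORTIONAL", "GC_NATURAL")
.excluded_categories <- c("EXCLUDED_NCD", "EXCLUDED_NEONATAL_ASPIRATION")
.all_categories <- c(
  .target_categories, .garbage_categories, .excluded_categories,
  "OUT_OF_UNIVERSE"
)

#' Cause-category labels
#'
#' `target_categories()` returns the seven categories eligible to receive
#' redistributed deaths; `external_targets()` the six external-cause subgroups
#' (i.e. without the pneumonia target); `garbage_categories()` the garbage
#' classes that the redistribution engine consumes.
#'
#' @return A character vector of category labels.
#' @export
target_categories <- function() .target_categories

#' @rdname target_categories
#' @export
external_targets <- function() setdiff(.target_categories, "PNEUMONIA_TARGET")

#' @rdname target_categories
#' @export
garbage_categories <- function() .garbage_categories

#' Normalize free-text ICD-10 codes
#'
#' Canonical form is an uppercase letter followed by two digits and an
#' optional third digit, with no dot (e.g. `"V011"`, `"X59"`). Normalization
#' is idempotent.
#'
#' @param raw Character vector of codes as found in microdata (may contain a
#'   dot after the third character, lowercase letters, stray whitespace).
#' @return Character vector of canonical codes, same length as `raw`.
#' @examples
#' normalize_icd10(c("V01.1", " x59", "W00"))
#' @export
normalize_icd10 <- function(raw) {
  x <- toupper(gsub("[[:space:].]", "", as.character(raw)))
  bad <- is.na(x) | !grepl("^[A-Z][0-9]{2}[0-9]?$", x)
  if (any(bad)) {
    idx <- which(bad)
    shown <- utils::head(idx, 5L)
    stop(
      "malformed ICD-10 code(s) at position(s) ",
      paste(shown, collapse = ", "),
      if (length(idx) > length(shown)) sprintf(" (and %d more)", length(idx) - length(shown)),
      ": ", paste(unique(raw[shown]), collapse = ", "),
      call. = FALSE
    )
  }
  x
}

# Integer index of a 4-character code: letter block * 1000 + digits.
.code_index <- function(code4) {
  (match(substr(code4, 1L, 1L), LETTERS) - 1L) * 1000L +
    as.integer(substr(code4, 2L, 4L))
}

.index_code <- function(idx) {
  paste0(LETTERS[idx %/% 1000L + 1L], sprintf("%03d", idx %% 1000L))
}

# Range endpoints as printed in cause lists: a 3-character start covers its
# "0" child, a 3-character end covers its "9" child.
.range_lo <- function(x) ifelse(nchar(x) == 3L, paste0(x, "0"), x)
.range_hi <- function(x) ifelse(nchar(x) == 3L, paste0(x, "9"), x)

# Chapter XX of ICD-10 (external causes): V010 .. Y899.
.chapter_xx <- function() .code_index("V010"):.code_index("Y899")

#' Build the ICD-10 cause map
#'
#' Expands a range table (columns `range_start`, `range_end`, `category`) into
#' a complete lookup over all syntactically valid 4-character codes. Range
#' endpoints are inclusive; where ranges overlap, the most specific (narrowest)
#' range wins, and a partial overlap between ranges with different categories
#' is a configuration error. Any chapter-XX code (V010-Y899) not covered by a
#' listed range falls to the residual garbage class `GC_PROPORTIONAL`; codes
#' outside chapter XX and not listed are `OUT_OF_UNIVERSE`.
#'
#' @param config A data frame with columns `range_start`, `range_end`,
#'   `category`, or a path to a CSV file with those columns. `NULL` (default)
#'   loads the map shipped with the package, which reproduces the study's
#'   published code lists.
#' @return An object of class `cause_map`: a list with the validated range
#'   `table`, the expanded `lookup` (named character vector over 4-character
#'   codes) and a `version` tag.
#' @examples
#' map <- build_cause_map()
#' classify_icd10(c("W05", "X60", "Y341"), map)
#' @export
build_cause_map <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "cause_map_default.csv", package = "gcredist")
  }
  tbl <- if (is.character(config)) {
    readr::read_csv(config, col_types = readr::cols(.default = readr::col_character()))
  } else {
    tibble::as_tibble(config)
  }
  required <- c("range_start", "range_end", "category")
  if (!all(required %in% names(tbl))) {
    stop("cause-map config needs columns: ", paste(required, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(unique(tbl$category), .all_categories)
  if (length(bad_cat)) {
    stop("unknown cause categories in config: ", paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  lo <- .code_index(.range_lo(normalize_icd10(tbl$range_start)))
  hi <- .code_index(.range_hi(normalize_icd10(tbl$range_end)))
  if (any(hi < lo)) {
    stop("cause-map ranges with end before start: ",
         paste(tbl$range_start[hi < lo], tbl$range_end[hi < lo], sep = "-", collapse = ", "),
         call. = FALSE)
  }
  width <- hi - lo + 1L

  # Partial overlaps (neither range contains the other) with different
  # categories are ambiguous; containment is resolved narrowest-wins below.
  n <- nrow(tbl)
  for (i in seq_len(n)) {
    j <- which(lo <= hi[i] & hi >= lo[i])
    j <- j[j > i]
    for (k in j) {
      contained <- (lo[k] >= lo[i] && hi[k] <= hi[i]) || (lo[i] >= lo[k] && hi[i] <= hi[k])
      if (!contained && tbl$category[i] != tbl$category[k]) {
        stop(sprintf(
          "overlapping cause-map ranges %s-%s (%s) and %s-%s (%s)",
          tbl$range_start[i], tbl$range_end[i], tbl$category[i],
          tbl$range_start[k], tbl$range_end[k], tbl$category[k]
        ), call. = FALSE)
      }
    }
  }

  lookup <- rep("OUT_OF_UNIVERSE", 26000L)
  lookup[.chapter_xx() + 1L] <- "GC_PROPORTIONAL"  # residual rule
  # widest first so that narrower (more specific) ranges overwrite
  for (i in order(width, decreasing = TRUE)) {
    lookup[(lo[i]:hi[i]) + 1L] <- tbl$category[i]
  }
  names(lookup) <- .index_code(0:25999)

  structure(
    list(table = tbl, lookup = lookup, version = "gbd-brasil-2010-2019"),
    class = "cause_map"
  )
}

#' Classify normalized ICD-10 codes
#'
#' A 4-character code is looked up directly; a 3-character record code inherits
#' the classification of its unspecified (".9") child, which matches registry
#' practice when certificates mix coding granularities.
#'
#' @param code Character vector of canonical codes (see [normalize_icd10()]).
#' @param map A `cause_map` from [build_cause_map()].
#' @return Character vector of category labels, one per code.
#' @export
classify_icd10 <- function(code, map) {
  stopifnot(inherits(map, "cause_map"))
  key <- ifelse(nchar(code) == 3L, paste0(code, "9"), code)
  out <- unname(map$lookup[key])
  if (anyNA(out)) {
    stop("unclassifiable code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @export
print.cause_map <- function(x, ...) {
  cat("<cause_map> version", x$version, "-", nrow(x$table), "ranges\n")
  tab <- sort(table(x$lookup[.chapter_xx() + 1L]), decreasing = TRUE)
  cat("chapter-XX composition:\n")
  print(tab)
  invisible(x)
}
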