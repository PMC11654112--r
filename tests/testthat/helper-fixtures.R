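# Shared fixtures, built in code.

default_map <- build_cause_map()

shipped_reclass <- function() {
  read_reclass_table(system.file("extdata", "reclass_fractions_synthetic.csv",
                                 package = "gcredist"))
}

shipped_factors <- function() {
  read_correction_factors(system.file("extdata", "correction_factors_synthetic.csv",
                                      package = "gcredist"))
}

# A small hand-sized record set: `n` per cause code, one stratum unless
# overridden.
mk_records <- function(causes, n = 1, uf = "SP", year = 2015,
                       sex = "male", age_group = "20-24", weight = 1) {
  tibble::tibble(
    year = year, uf = uf, sex = sex, age_group = age_group,
    cause = rep(causes, each = n), weight = weight
  )
}

# Brute-force per-record redistribution: the independent oracle for the
# vectorized engine. Walks records one at a time and splits each garbage
# record's weight using the per-stratum plan functions directly.
brute_force_redistribute <- function(records, map, reclass = NULL,
                                     policy = default_redistribution_policy(),
                                     stratum_vars = c("uf", "year", "sex", "age_group")) {
  records <- gcredist:::ensure_category(records, map)
  sources <- intersect(unique(records$cause_category), garbage_categories())
  if (!is.null(reclass) && "PNEUMONIA_TARGET" %in% reclass$garbage &&
      "PNEUMONIA_TARGET" %in% records$cause_category) {
    sources <- c(sources, "PNEUMONIA_TARGET")
  }
  is_src <- records$cause_category %in% sources
  targets <- records[!is_src, , drop = FALSE]
  totals <- tapply(targets$weight, targets$cause_category, sum)
  acc <- as.list(totals)
  for (i in which(is_src)) {
    rec <- records[i, ]
    cls <- rec$cause_category
    stratum <- as.list(rec[stratum_vars])
    if (policy$criterion[[cls]] == "proportional") {
      w <- proportional_weights(targets, stratum,
                                destinations = policy$destinations[[cls]] %||% external_targets())
    } else {
      key <- gcredist:::.reclass_key(rec$cause, cls, reclass)
      strat_cols <- intersect(c("sex", "age_group", "uf"), names(reclass))
      w <- investigation_weights(reclass, key,
                                 stratum = if (length(strat_cols)) stratum else NULL,
                                 destinations = policy$destinations[[cls]])
    }
    for (d in names(w)) {
      acc[[d]] <- (acc[[d]] %||% 0) + rec$weight * w[[d]]
    }
  }
  unlist(acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

category_totals <- function(records) {
  out <- tapply(records$weight, records$cause_category, sum)
  setNames(as.numeric(out), dimnames(out)[[1]])[sort(names(out))]
}
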