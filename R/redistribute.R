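#' Read and validate an investigated-death reclassification table
#'
#' The table gives, for each garbage code (e.g. `X59`, `Y34`) or garbage class
#' (e.g. `GC_NATURAL`, `PNEUMONIA_TARGET`), the fraction of investigated
#' deaths reclassified into each destination. Destinations are the seven
#' target categories plus `NATURAL_RESIDUAL` (deaths leaving the external
#' universe). Fractions must sum to 1 within each (garbage, stratum) group;
#' optional stratification columns `sex`, `age_group` and `uf` are supported.
#'
#' @param x Path to a CSV with columns `garbage`, `destination`, `fraction`
#'   (optionally `sex`, `age_group`, `uf`), or a data frame with the same
#'   columns.
#' @return A validated tibble of class `reclass_table`.
#' @export
read_reclass_table <- function(x) {
  tbl <- if (is.character(x)) {
    readr::read_csv(x, col_types = readr::cols(
      fraction = readr::col_double(), .default = readr::col_character()
    ))
  } else {
    tibble::as_tibble(x)
  }
  required <- c("garbage", "destination", "fraction")
  if (!all(required %in% names(tbl))) {
    stop("reclassification table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  legal_dest <- c(.target_categories, "NATURAL_RESIDUAL")
  bad <- setdiff(unique(tbl$destination), legal_dest)
  if (length(bad)) {
    stop("illegal reclassification destinations: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(tbl$fraction < 0 | tbl$fraction > 1)) {
    stop("reclassification fractions must lie in [0, 1]", call. = FALSE)
  }
  strat <- intersect(c("sex", "age_group", "uf"), names(tbl))
  sums <- tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("garbage", strat)))) |>
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  off <- abs(sums$s - 1) > 1e-9
  if (any(off)) {
    stop("reclassification fractions do not sum to 1 for: ",
         paste(sums$garbage[off], collapse = ", "), call. = FALSE)
  }
  class(tbl) <- c("reclass_table", class(tbl))
  tbl
}

# Coarsening chain used when a redistribution stratum has no target deaths:
# drop age group, then sex, then state (national pool), then year.
.stratum_chain <- function(stratum_vars) {
  chain <- list(stratum_vars)
  for (d in intersect(c("age_group", "sex", "municipality", "uf", "year"), stratum_vars)) {
    stratum_vars <- setdiff(stratum_vars, d)
    chain <- c(chain, list(stratum_vars))
  }
  chain
}

#' Proportional redistribution weights
#'
#' Weight of each destination category equals its share of total target weight
#' in the narrowest non-empty stratum, falling back to coarser strata
#' (dropping age group, sex, state, year in that order) when the requested
#' stratum holds no target deaths.
#'
#' @param targets Tibble of target-cause records (columns `cause_category`,
#'   `weight`, plus stratum columns).
#' @param stratum Named list or one-row data frame selecting the stratum
#'   (e.g. `list(uf = "SP", year = 2015, sex = "male", age_group = "20-24")`);
#'   `NULL` uses the whole pool.
#' @param destinations Categories the garbage class may flow to; defaults to
#'   the six external target subgroups.
#' @return Named numeric vector of weights over `destinations`, summing to 1.
#' @export
proportional_weights <- function(targets, stratum = NULL,
                                 destinations = external_targets()) {
  targets <- tibble::as_tibble(targets)
  targets <- targets[targets$cause_category %in% destinations, , drop = FALSE]
  stratum_vars <- if (is.null(stratum)) character(0) else names(stratum)
  stratum <- as.list(stratum)
  for (keys in .stratum_chain(stratum_vars)) {
    pool <- targets
    for (k in keys) pool <- pool[!is.na(pool[[k]]) & pool[[k]] == stratum[[k]], , drop = FALSE]
    tot <- sum(pool$weight)
    if (tot > 0) {
      w <- tapply(pool$weight, factor(pool$cause_category, levels = destinations), sum)
      w[is.na(w)] <- 0
      return(setNames(as.numeric(w) / tot, destinations))
    }
  }
  stop("no target deaths at any fallback level for stratum: ",
       paste(names(stratum), unlist(stratum), sep = "=", collapse = ", "),
       call. = FALSE)
}

#' Investigated-death reclassification weights
#'
#' Looks up the reclassification fractions for a garbage code (or, failing
#' that, its class) in a [read_reclass_table()] table, optionally matching a
#' stratified row set, and renormalizes when the configured destination subset
#' excludes some listed destination.
#'
#' @param table A `reclass_table`.
#' @param garbage Garbage code (e.g. `"X59"`) or class label.
#' @param stratum Optional named list with `sex`/`age_group`/`uf` used when
#'   the table is stratified; unstratified rows (NA in those columns) act as
#'   the global fallback.
#' @param destinations Optional subset of destinations to keep; fractions are
#'   renormalized over it.
#' @return Named numeric vector of fractions summing to 1.
#' @export
investigation_weights <- function(table, garbage, stratum = NULL,
                                  destinations = NULL) {
  rows <- table[table$garbage == garbage, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop("no reclassification rows for '", garbage,
         "'; consider the proportional criterion for this class", call. = FALSE)
  }
  strat_cols <- intersect(c("sex", "age_group", "uf"), names(table))
  if (length(strat_cols) && !is.null(stratum)) {
    specific <- rows
    for (k in intersect(strat_cols, names(stratum))) {
      specific <- specific[!is.na(specific[[k]]) & specific[[k]] == stratum[[k]], , drop = FALSE]
    }
    if (nrow(specific) == 0) {
      # global fallback: rows with no stratification
      specific <- rows
      for (k in strat_cols) specific <- specific[is.na(specific[[k]]), , drop = FALSE]
    }
    rows <- specific
  } else if (length(strat_cols)) {
    for (k in strat_cols) rows <- rows[is.na(rows[[k]]), , drop = FALSE]
  }
  if (nrow(rows) == 0) {
    stop("no reclassification rows for '", garbage, "' at the requested stratum",
         call. = FALSE)
  }
  w <- setNames(rows$fraction, rows$destination)
  if (!is.null(destinations)) {
    w <- w[names(w) %in% destinations]
    if (!length(w) || sum(w) == 0) {
      stop("destination restriction removes every reclassification destination for '",
           garbage, "'", call. = FALSE)
    }
    w <- w / sum(w)
  }
  w
}

#' Default redistribution policy
#'
#' The shipped policy follows the study's choices: unspecified-exposure and
#' undetermined-intent garbage (X59/Y34), the pneumonia class and the natural
#' garbage class use investigated-death reclassification fractions; every
#' other external garbage code is redistributed proportionally to the local
#' target-cause composition. Destination sets restrict where each class may
#' flow; `NULL` means "as listed in the reclassification table".
#'
#' @return A list with elements `criterion` (named character) and
#'   `destinations` (named list).
#' @export
default_redistribution_policy <- function() {
  list(
    criterion = c(
      GC_PROPORTIONAL  = "proportional",
      GC_INVESTIGATION = "investigation",
      GC_NATURAL       = "investigation",
      PNEUMONIA_TARGET = "investigation"
    ),
    destinations = list(
      GC_PROPORTIONAL  = external_targets(),
      GC_INVESTIGATION = NULL,
      GC_NATURAL       = NULL,
      PNEUMONIA_TARGET = NULL
    )
  )
}

#' Redistribute garbage-coded deaths into target causes
#'
#' Single-pass redistribution over a frozen target distribution: target-cause
#' records pass through unchanged, and each garbage record's weight is split
#' across destination categories according to its class's plan (proportional
#' or investigation, per `policy`). Pneumonia-coded deaths are treated as a
#' redistribution source only when the reclassification table carries rows for
#' `PNEUMONIA_TARGET`; their residual fraction stays in the pneumonia target.
#' Total weight is conserved, counting the `NATURAL_RESIDUAL` outflow.
#'
#' @param records Classified records (columns `cause_category`, `weight`,
#'   stratum columns; `cause` used to key investigation rows by code).
#' @param map A `cause_map`, used only if `cause_category` is absent.
#' @param reclass A [read_reclass_table()] table; required when any class
#'   present uses the investigation criterion.
#' @param policy See [default_redistribution_policy()].
#' @param stratum_vars Columns defining the proportional-weight stratum.
#' @return Tibble of records whose categories are target causes or
#'   `NATURAL_RESIDUAL` only; redistributed rows carry `cause = NA`.
#' @export
redistribute_garbage <- function(records, map = NULL, reclass = NULL,
                                 policy = default_redistribution_policy(),
                                 stratum_vars = c("uf", "year", "sex", "age_group")) {
  records <- ensure_category(records, map)
  stratum_vars <- intersect(stratum_vars, names(records))

  src_classes <- intersect(unique(records$cause_category), .garbage_categories)
  if ("PNEUMONIA_TARGET" %in% records$cause_category &&
      !is.null(reclass) && "PNEUMONIA_TARGET" %in% reclass$garbage) {
    src_classes <- c(src_classes, "PNEUMONIA_TARGET")
  }
  leftover <- setdiff(unique(records$cause_category),
                      c(.target_categories, src_classes))
  if (length(leftover)) {
    stop("records outside the redistribution universe: ",
         paste(leftover, collapse = ", "),
         "; run apply_sim_universe() first", call. = FALSE)
  }

  is_source <- records$cause_category %in% src_classes
  frozen_targets <- records[!is_source, , drop = FALSE]
  garbage <- records[is_source, , drop = FALSE]
  if (nrow(garbage) == 0) return(records)

  # validate plans up-front so errors precede any mutation
  for (cls in src_classes) {
    crit <- policy$criterion[[cls]]
    if (is.null(crit)) stop("no redistribution criterion configured for ", cls, call. = FALSE)
    if (crit == "investigation") {
      if (is.null(reclass)) {
        stop("class ", cls, " uses the investigation criterion but no ",
             "reclassification table was given", call. = FALSE)
      }
      codes <- unique(.reclass_key(garbage$cause[garbage$cause_category == cls], cls, reclass))
      missing <- codes[!codes %in% reclass$garbage]
      if (length(missing)) {
        stop("no reclassification rows for: ", paste(missing, collapse = ", "),
             "; consider the proportional criterion", call. = FALSE)
      }
    }
  }

  redistributed <- lapply(src_classes, function(cls) {
    chunk <- garbage[garbage$cause_category == cls, , drop = FALSE]
    crit <- policy$criterion[[cls]]
    dests <- policy$destinations[[cls]]
    if (crit == "proportional") {
      .redistribute_proportional(chunk, frozen_targets, stratum_vars,
                                 dests %||% external_targets())
    } else {
      .redistribute_investigation(chunk, reclass, cls, dests, stratum_vars)
    }
  })

  out <- dplyr::bind_rows(c(list(frozen_targets), redistributed))
  tibble::as_tibble(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Key used to look rows up in the reclassification table: the record's
# 3-character code when the table carries rows for it, else its class label.
.reclass_key <- function(cause, cls, reclass) {
  code3 <- substr(cause, 1L, 3L)
  ifelse(!is.na(code3) & code3 %in% reclass$garbage, code3, cls)
}

# Vectorized proportional split: totals per garbage stratum joined to target
# shares at the narrowest fallback level with positive target weight.
.redistribute_proportional <- function(chunk, targets, stratum_vars, destinations) {
  pool <- targets[targets$cause_category %in% destinations, , drop = FALSE]
  if (sum(pool$weight) == 0) {
    stop("no target deaths at any fallback level to receive proportional garbage",
         call. = FALSE)
  }
  g <- chunk |>
    dplyr::group_by(dplyr::across(dplyr::all_of(stratum_vars))) |>
    dplyr::summarise(.g = sum(.data$weight), .groups = "drop")
  out <- list()
  for (keys in .stratum_chain(stratum_vars)) {
    if (nrow(g) == 0) break
    shares <- pool |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "cause_category")))) |>
      dplyr::summarise(.w = sum(.data$weight), .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::mutate(.share = .data$.w / sum(.data$.w)) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(keys), "cause_category", ".share")
    if (length(keys)) {
      hit <- dplyr::inner_join(g, dplyr::distinct(shares[keys]), by = keys)
      g <- dplyr::anti_join(g, shares, by = keys)
      m <- dplyr::inner_join(hit, shares, by = keys, relationship = "many-to-many")
    } else {
      m <- dplyr::cross_join(g, shares)
      g <- g[0, , drop = FALSE]
    }
    if (nrow(m)) {
      m$weight <- m$.g * m$.share
      m$cause <- NA_character_
      out <- c(out, list(m[c(stratum_vars[stratum_vars %in% names(m)],
                             "cause", "cause_category", "weight")]))
    }
  }
  dplyr::bind_rows(out)
}

.redistribute_investigation <- function(chunk, reclass, cls, destinations, stratum_vars) {
  chunk$.key <- .reclass_key(chunk$cause, cls, reclass)
  strat_cols <- intersect(intersect(c("sex", "age_group", "uf"), names(reclass)),
                          stratum_vars)
  g <- chunk |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(".key", stratum_vars)))) |>
    dplyr::summarise(.g = sum(.data$weight), .groups = "drop")
  rows <- lapply(seq_len(nrow(g)), function(i) {
    stratum <- as.list(g[i, stratum_vars, drop = FALSE])
    w <- investigation_weights(reclass, g$.key[i],
                               stratum = if (length(strat_cols)) stratum else NULL,
                               destinations = destinations)
    res <- g[rep(i, length(w)), stratum_vars, drop = FALSE]
    res$cause <- NA_character_
    res$cause_category <- names(w)
    res$weight <- g$.g[i] * as.numeric(w)
    res
  })
  dplyr::bind_rows(rows)
}

#' Total-variation distance between two redistribution plans
#'
#' @param p,q Named weight vectors over destination categories.
#' @return Half the L1 distance over the union of destinations.
#' @export
tv_distance <- function(p, q) {
  dests <- union(names(p), names(q))
  p <- setNames(ifelse(is.na(p[dests]), 0, p[dests]), dests)
  q <- setNames(ifelse(is.na(q[dests]), 0, q[dests]), dests)
  0.5 * sum(abs(p - q))
}

#' Compare the two weighting criteria for a garbage class
#'
#' Reports the diagnostics the method uses to choose between the proportional
#' and investigated-death criteria — the size of the garbage class and the
#' divergence between the two candidate plans — together with the shipped
#' default choice for that class.
#'
#' @param garbage_class Class label (e.g. `"GC_INVESTIGATION"`).
#' @param proportional_plan,investigation_plan Named weight vectors.
#' @param n_deaths Total garbage weight in the class.
#' @return A list with `recommendation`, `n_deaths` and `tv_distance`.
#' @export
choose_criterion <- function(garbage_class, proportional_plan,
                             investigation_plan, n_deaths) {
  default <- default_redistribution_policy()$criterion
  list(
    recommendation = if (garbage_class %in% names(default))
      unname(default[[garbage_class]]) else "proportional",
    n_deaths = n_deaths,
    tv_distance = tv_distance(proportional_plan, investigation_plan)
  )
}
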