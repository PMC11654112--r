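test_that("proportional weights are normalized target shares", {
  targets <- dplyr::bind_rows(
    mk_records("W109", n = 30),  # falls
    mk_records("X954", n = 70)   # homicide
  )
  targets$cause_category <- classify_icd10(targets$cause, default_map)
  w <- proportional_weights(targets)
  expect_equal(sum(w), 1)
  expect_equal(unname(w["FALLS"]), 0.3)
  expect_equal(unname(w["HOMICIDE"]), 0.7)

  single <- mk_records("X700", n = 12)
  single$cause_category <- "SUICIDE"
  w1 <- proportional_weights(single)
  expect_equal(unname(w1["SUICIDE"]), 1)
})

test_that("proportional weights fall back to coarser strata when empty", {
  targets <- dplyr::bind_rows(
    mk_records("V031", n = 50, uf = "SP"),
    mk_records("W109", n = 50, uf = "SP")
  )
  targets$cause_category <- classify_icd10(targets$cause, default_map)
  w <- proportional_weights(targets, stratum = list(uf = "RJ", year = 2015,
                                                    sex = "male", age_group = "20-24"))
  expect_equal(unname(w["TRANSPORT_INJURY"]), 0.5)
  expect_equal(unname(w["FALLS"]), 0.5)
  expect_error(
    proportional_weights(targets[0, ], stratum = list(uf = "RJ")),
    "no target deaths"
  )
})

test_that("investigation weights return table fractions and renormalize", {
  tbl <- read_reclass_table(tibble::tibble(
    garbage = "Y34",
    destination = c("HOMICIDE", "SUICIDE", "NATURAL_RESIDUAL"),
    fraction = c(0.5, 0.3, 0.2)
  ))
  w <- investigation_weights(tbl, "Y34")
  expect_equal(unname(w["HOMICIDE"]), 0.5)
  dropped <- investigation_weights(tbl, "Y34",
                                   destinations = c("HOMICIDE", "SUICIDE"))
  expect_equal(unname(dropped), c(0.625, 0.375))
  expect_error(investigation_weights(tbl, "X59"), "proportional")

  degenerate <- read_reclass_table(tibble::tibble(
    garbage = "X59", destination = "FALLS", fraction = 1
  ))
  expect_equal(unname(investigation_weights(degenerate, "X59")["FALLS"]), 1)
})

test_that("reclassification tables are validated on load", {
  expect_error(read_reclass_table(tibble::tibble(
    garbage = "Y34", destination = c("HOMICIDE", "SUICIDE"), fraction = c(0.6, 0.6)
  )), "sum to 1")
  expect_error(read_reclass_table(tibble::tibble(
    garbage = "Y34", destination = "GC_PROPORTIONAL", fraction = 1
  )), "illegal")
  sums <- shipped_reclass() |>
    dplyr::group_by(garbage) |>
    dplyr::summarise(s = sum(fraction))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("an undetermined-intent block sends its homicide fraction as expected", {
  recs <- dplyr::bind_rows(
    mk_records("X954", n = 50), mk_records("W109", n = 50),
    mk_records("Y340", n = 100)
  )
  reclass <- shipped_reclass()
  out <- redistribute_garbage(recs, default_map, reclass)
  got <- category_totals(out)
  # 100 Y34 deaths, 39% reclassified to homicide
  expect_equal(unname(got["HOMICIDE"]), 50 + 39)
  expect_equal(sum(out$weight), 200, tolerance = 1e-12)
})

test_that("redistribution conserves weight and leaves no garbage behind", {
  set.seed(11)
  n <- 10000
  pool <- c("X954", "W109", "X700", "V031", "V905", "X099",
            "Y872", "X599", "Y340", "J150", "A410", "R99", "G443")
  recs <- tibble::tibble(
    year = sample(2010:2011, n, TRUE),
    uf = sample(c("SP", "RJ", "MG", "BA"), n, TRUE),
    sex = sample(c("male", "female"), n, TRUE),
    age_group = sample(default_age_bins()[8:12], n, TRUE),
    cause = sample(pool, n, TRUE),
    weight = stats::runif(n, 0.5, 2)
  )
  out <- redistribute_garbage(recs, default_map, shipped_reclass())
  expect_equal(sum(out$weight) / sum(recs$weight), 1, tolerance = 1e-9)
  expect_length(intersect(unique(out$cause_category), garbage_categories()), 0)
  expect_true(all(out$cause_category %in% c(target_categories(), "NATURAL_RESIDUAL")))
})

test_that("no garbage present means identity, and absent plans abort early", {
  clean <- mk_records(c("X954", "W109"), n = 5)
  out <- redistribute_garbage(clean, default_map)
  expect_equal(category_totals(out),
               category_totals(gcredist:::ensure_category(clean, default_map)))

  dirty <- dplyr::bind_rows(clean, mk_records("Y340", n = 2))
  expect_error(redistribute_garbage(dirty, default_map), "reclassification table")
})

test_that("engine output equals brute-force per-record enumeration", {
  set.seed(23)
  for (rep in 1:3) {
    n <- sample(40:100, 1)
    recs <- tibble::tibble(
      year = sample(2010:2011, n, TRUE),
      uf = sample(c("SP", "RJ"), n, TRUE),
      sex = sample(c("male", "female"), n, TRUE),
      age_group = sample(c("20-24", "25-29"), n, TRUE),
      cause = sample(c("X954", "W109", "X700", "V031", "Y872", "X599", "Y340"),
                     n, TRUE, prob = c(0.25, 0.2, 0.15, 0.15, 0.1, 0.08, 0.07)),
      weight = stats::runif(n, 0.5, 2)
    )
    reclass <- shipped_reclass()
    engine <- category_totals(redistribute_garbage(recs, default_map, reclass))
    oracle <- brute_force_redistribute(recs, default_map, reclass)
    oracle <- oracle[order(names(oracle))]
    oracle <- oracle[oracle > 0]
    expect_equal(engine[names(oracle)], oracle, tolerance = 1e-12)
  }
})

test_that("raising a stratum's homicide share weakly raises its homicide inflow", {
  base <- dplyr::bind_rows(mk_records("X954", n = 50), mk_records("W109", n = 50))
  more <- dplyr::bind_rows(mk_records("X954", n = 70), mk_records("W109", n = 50))
  garb <- mk_records("Y872", n = 10)
  out_base <- redistribute_garbage(dplyr::bind_rows(base, garb), default_map)
  out_more <- redistribute_garbage(dplyr::bind_rows(more, garb), default_map)
  inflow <- function(out, n_direct) sum(out$weight[out$cause_category == "HOMICIDE"]) - n_direct
  expect_gte(inflow(out_more, 70), inflow(out_base, 50))
})

test_that("criterion diagnostics report size and plan divergence", {
  same <- c(HOMICIDE = 0.5, FALLS = 0.5)
  expect_equal(choose_criterion("GC_PROPORTIONAL", same, same, 10)$tv_distance, 0)
  expect_equal(tv_distance(c(A = 1, B = 0), c(A = 0, B = 1)), 1)
  expect_equal(tv_distance(c(A = 0.6, B = 0.4), c(A = 0.5, B = 0.5)), 0.1)
  d <- choose_criterion("GC_INVESTIGATION", same, c(HOMICIDE = 1), 42)
  expect_equal(d$recommendation, "investigation")
  expect_equal(d$n_deaths, 42)
  expect_equal(d$tv_distance, 0.5)
})

test_that("pneumonia-coded deaths redistribute only when the table covers them", {
  recs <- dplyr::bind_rows(
    mk_records("X954", n = 50), mk_records("W109", n = 30),
    mk_records("J150", n = 20)
  )
  # without pneumonia rows the class passes through as a target
  no_rows <- read_reclass_table(tibble::tibble(
    garbage = "Y34", destination = "HOMICIDE", fraction = 1
  ))
  kept <- redistribute_garbage(recs, default_map, no_rows)
  expect_equal(sum(kept$weight[kept$cause_category == "PNEUMONIA_TARGET"]), 20)
  # with rows, the residual fraction stays pneumonia and the rest migrates
  out <- redistribute_garbage(recs, default_map, shipped_reclass())
  expect_equal(sum(out$weight[out$cause_category == "PNEUMONIA_TARGET"]), 14)
  expect_equal(sum(out$weight), 100, tolerance = 1e-12)
})
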