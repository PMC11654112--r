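test_that("standardized rate reduces to the crude rate under the standard structure", {
  pop <- c(`0-4` = 30000, `5-9` = 50000, `10-14` = 20000)
  deaths <- c(`0-4` = 3, `5-9` = 10, `10-14` = 8)
  crude <- sum(deaths) / sum(pop) * 1e5
  expect_equal(direct_standardized_rate(deaths, pop, pop), crude)
  # invariance to proportional scaling of the standard
  expect_equal(direct_standardized_rate(deaths, pop, pop * 7.3), crude)
})

test_that("standardized rate is the standard-weighted mean of bin rates", {
  # two bins with rates 10 and 30 per 100k, equal standard weights
  expect_equal(
    direct_standardized_rate(c(10, 30), c(1e5, 1e5), c(0.5, 0.5)), 20
  )
  expect_equal(direct_standardized_rate(c(0, 0), c(1e5, 1e5), c(1, 1)), 0)
  expect_error(
    direct_standardized_rate(c(a = 1), c(b = 1e5), c(b = 1)),
    "age-bin mismatch"
  )
  expect_error(direct_standardized_rate(1, 0, 1), "positive")
})

test_that("percent variation reproduces the published worked examples", {
  expect_equal(round_half_up(percent_variation(66.5, 57.8), 1), -13.1)
  expect_equal(round_half_up(percent_variation(103.8, 68.3), 1), -34.2)
  expect_equal(percent_variation(50, 50), 0)
  expect_warning(out <- percent_variation(0, 10), "zero")
  expect_true(is.na(out))
})

test_that("correction ratios reproduce the published worked examples", {
  expect_equal(round_half_up(correction_ratio(75.6, 66.5), 2), 1.14)
  expect_equal(round_half_up(correction_ratio(67.4, 57.8), 2), 1.17)
  expect_equal(correction_ratio(42, 42), 1)
  expect_warning(out <- correction_ratio(10, 0), "zero")
  expect_true(is.na(out))
})

test_that("rounding is half away from zero at report precision", {
  expect_equal(round_half_up(c(1.25, -1.25, 2.5, -2.5), 1), c(1.3, -1.3, 2.5, -2.5))
  expect_equal(round_half_up(c(1.125, -1.125), 2), c(1.13, -1.13))
})

test_that("loess reproduces constants and exact lines", {
  years <- 2010:2019
  const <- loess_trend(years, rep(5, 10))
  expect_equal(const$smoothed, rep(5, 10), tolerance = 1e-8)
  line <- loess_trend(years, 3 + 2 * (years - 2010), span = 0.6, degree = 1)
  expect_lt(max(abs(line$smoothed - line$rate)), 1e-8)
  expect_error(loess_trend(2010:2011, c(1, 2)), "at least")
  expect_error(loess_trend(years, rep(1, 10), span = 0), "span")
})

test_that("loess matches a textbook tricube local regression", {
  # independent oracle: tricube-weighted least squares at each point, using
  # the floor(span*n) nearest neighbours
  tricube_fit <- function(x, y, span, x0) {
    n <- length(x)
    q <- floor(span * n)
    sapply(x0, function(z) {
      d <- abs(x - z)
      dq <- sort(d)[q]
      w <- (1 - pmin(d / dq, 1)^3)^3
      fit <- stats::lm.wfit(cbind(1, x - z), y, w)
      fit$coefficients[1]
    })
  }
  set.seed(99)
  x <- 2010:2019
  y <- sin((x - 2010) / 2) * 10 + 60 + stats::rnorm(10)
  got <- loess_trend(x, y, span = 0.75, degree = 1)$smoothed
  want <- tricube_fit(x, y, 0.75, x)
  expect_equal(got, unname(want), tolerance = 1e-6)
})

test_that("rankings order by rate with alphabetical tie-break, deltas sum to zero", {
  tb <- published_rates()
  states <- tb[tb$uf != "BR", ]
  rk <- rank_ufs(tibble::tibble(uf = states$uf, rate = states$gbdbr_2019))
  expect_equal(rk$uf[rk$rank == 1], "RR")
  expect_equal(rk$uf[rk$rank == 2], "TO")

  ties <- tibble::tibble(uf = uf_codes(), rate = 10)
  expect_equal(rank_ufs(ties)$uf, sort(uf_codes()))

  cmp <- rank_ufs(tibble::tibble(uf = states$uf, rate = states$gbdbr_2019),
                  tibble::tibble(uf = states$uf, rate = states$sim_2019))
  expect_equal(sum(cmp$delta), 0)
  expect_error(rank_ufs(ties[-1, ]), "missing units")
})

test_that("rate ratios and percent variations are mutually consistent on exact rates", {
  r0_sim <- 66.5; r1_sim <- 57.8; r0_gb <- 75.6; r1_gb <- 67.4
  lhs <- correction_ratio(r1_gb, r1_sim) / correction_ratio(r0_gb, r0_sim)
  rhs <- (1 + percent_variation(r0_gb, r1_gb) / 100) /
    (1 + percent_variation(r0_sim, r1_sim) / 100)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("record-level standardization matches the vector formula", {
  pop <- tidyr::expand_grid(uf = c("SP", "RJ"), year = c(2010, 2015),
                            sex = c("male", "female"),
                            age_group = c("20-24", "25-29"))
  pop$pop <- c(rep(50000, 8), rep(40000, 8))
  recs <- dplyr::bind_rows(
    mk_records("X954", n = 10, uf = "SP", year = 2015, age_group = "20-24"),
    mk_records("X954", n = 20, uf = "SP", year = 2015, age_group = "25-29")
  )
  recs$cause_category <- "HOMICIDE"
  got <- standardized_rates(recs, pop, by = c("uf", "year"))
  sp <- got$rate[got$uf == "SP" & got$year == 2015]
  # standard (2010, both sexes, both ufs) is uniform over the two bins;
  # SP 2015 person-years per bin collapse over sex to 100000
  want <- direct_standardized_rate(c(10, 20), c(100000, 100000), c(0.5, 0.5))
  expect_equal(sp, want)
})
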