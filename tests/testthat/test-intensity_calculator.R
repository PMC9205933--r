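test_that("year windows are half-open with day 365 in year 2", {
  ex <- tibble::tibble(ingredient = "bevacizumab", day = c(0L, 30L, 364L))
  expect_equal(count_injections(ex, "bevacizumab", 1), 3)
  ex365 <- tibble::tibble(ingredient = "bevacizumab", day = 365L)
  expect_equal(count_injections(ex365, "bevacizumab", 1), 0)
  expect_equal(count_injections(ex365, "bevacizumab", 2), 1)
  dup <- tibble::tibble(ingredient = "bevacizumab", day = c(10L, 10L))
  expect_equal(count_injections(dup, "bevacizumab", 1), 1)
  expect_equal(count_injections(dup, "bevacizumab", 1, same_day_dedup = FALSE),
               2)
  expect_equal(count_injections(dup, "ALL", 1), 1)
  expect_equal(year_window(2), c(365L, 730L))
})

# two anti-VEGF-first patients in one era: q1 with 3 bevacizumab year-1
# injections, 1 in year 2, followed 800 d; q2 with 1 year-1 injection,
# followed 200 d
two_patient_tables <- function() {
  idx <- as.Date("2013-03-01")
  cdm_tables(
    person = raw_person(c("q1", "q2")),
    drug_exposure = dplyr::bind_rows(
      raw_drug("q1", "BEV01", idx + c(0, 40, 100, 400)),
      raw_drug("q2", "BEV01", idx)),
    condition_occurrence = dplyr::bind_rows(
      raw_cond("q1", "RVO01", idx + 10),
      raw_cond("q2", "RVO01", idx + 10)),
    observation_period = dplyr::bind_rows(
      raw_obs("q1", idx, idx + 800),
      raw_obs("q2", idx, idx + 200)))
}

test_that("intensity denominators follow the year-1/year-2 rules", {
  t <- two_patient_tables()
  b <- build_cohort(t)
  it <- intensity_table(b$cohort, t)
  cell <- function(stratum, drug, yr) {
    it[it$stratum == stratum & it$drug == drug & it$year_index == yr, ]
  }
  expect_equal(cell("anti_VEGF_first", "ALL", 1)$n, 2L)
  expect_equal(cell("anti_VEGF_first", "ALL", 1)$mean, 2.0)
  expect_equal(cell("anti_VEGF_first", "ALL", 2)$n, 1L)
  expect_equal(cell("anti_VEGF_first", "ALL", 2)$mean, 1.0)
  expect_equal(cell("anti_VEGF_first", "bevacizumab", 1)$mean, 2.0)
  expect_equal(cell("anti_VEGF_first", "bevacizumab", 2)$n, 1L)
  expect_equal(cell("anti_VEGF_first", "bevacizumab", 2)$mean, 1.0)
  # empty steroid-first stratum is emitted with NA means
  expect_equal(cell("steroid_first", "ALL", 1)$n, 0L)
  expect_true(is.na(cell("steroid_first", "ALL", 1)$mean))
})

test_that("the two-year sensitivity scope restricts both columns first", {
  t <- two_patient_tables()
  b <- build_cohort(t)
  it <- intensity_table(b$cohort, t, intensity_config("min_2y_followup"))
  all_rows <- it[it$drug == "ALL" & it$stratum == "all", ]
  expect_equal(all_rows$n, c(1L, 1L))  # only q1 (800 d) remains, both years
  expect_equal(all_rows$mean, c(3.0, 1.0))
  # every ALL row shares one denominator across years
  per <- split(it[it$drug == "ALL", ],
               paste(it$era[it$drug == "ALL"], it$stratum[it$drug == "ALL"]))
  for (p in per) expect_equal(p$n[p$year_index == 1], p$n[p$year_index == 2])
})

test_that("an empty cohort yields an empty intensity table", {
  t <- cdm_tables()
  b <- build_cohort(t)
  it <- intensity_table(b$cohort, t)
  expect_equal(nrow(it), 0)
  expect_named(it, c("era", "stratum", "drug", "year_index", "n", "total",
                     "mean"))
})

test_that("injection totals are conserved between ALL and per-drug rows", {
  sim <- simulate_cdm(simulation_config(n_patients = 600, seed = 303))
  b <- build_cohort(sim$tables)
  ex <- cohort_exposures(sim$tables, b$cohort)
  # with stratum-wide denominators the ALL row equals the per-drug sum in
  # both years; with received-in-year-1 denominators it holds in year 1
  it_s <- intensity_table(b$cohort, ex,
                          intensity_config(drug_row_denominator =
                                             "all_in_stratum"))
  agg <- dplyr::summarise(
    dplyr::group_by(it_s[it_s$drug != "ALL", ],
                    era, stratum, year_index),
    total = sum(total), .groups = "drop")
  all_rows <- it_s[it_s$drug == "ALL", c("era", "stratum", "year_index",
                                         "total")]
  expect_equal(dplyr::arrange(agg, era, stratum, year_index),
               dplyr::arrange(all_rows, era, stratum, year_index))

  it_r <- intensity_table(b$cohort, ex, intensity_config())
  agg1 <- dplyr::summarise(
    dplyr::group_by(it_r[it_r$drug != "ALL" & it_r$year_index == 1, ],
                    era, stratum),
    total = sum(total), .groups = "drop")
  all1 <- it_r[it_r$drug == "ALL" & it_r$year_index == 1,
               c("era", "stratum", "total")]
  expect_equal(dplyr::arrange(agg1, era, stratum),
               dplyr::arrange(all1, era, stratum))
})

test_that("year-2 denominators never exceed year-1 denominators", {
  sim <- simulate_cdm(simulation_config(n_patients = 600, seed = 304))
  b <- build_cohort(sim$tables)
  for (scope in c("all_patients", "min_2y_followup")) {
    it <- intensity_table(b$cohort, sim$tables, intensity_config(scope))
    wide <- tidyr::pivot_wider(it[, c("era", "stratum", "drug", "year_index",
                                      "n")],
                               names_from = "year_index", values_from = "n")
    expect_true(all(wide$`2` <= wide$`1`))
  }
})

test_that("class-stratum denominators sum to the all-strata denominator", {
  sim <- simulate_cdm(simulation_config(n_patients = 600, seed = 305))
  b <- build_cohort(sim$tables)
  it <- intensity_table(b$cohort, sim$tables)
  all_rows <- it[it$drug == "ALL", ]
  for (e in unique(all_rows$era)) {
    for (yr in 1:2) {
      n_of <- function(s) all_rows$n[all_rows$era == e &
                                       all_rows$stratum == s &
                                       all_rows$year_index == yr]
      expect_equal(n_of("anti_VEGF_first") + n_of("steroid_first"),
                   n_of("all"))
    }
  }
})

test_that("year-2 persistence classifies patients by treatment class", {
  idx <- as.Date("2013-03-01")
  t <- cdm_tables(
    person = raw_person(c("r1", "r2", "r3")),
    drug_exposure = dplyr::bind_rows(
      raw_drug("r1", "BEV01", idx + c(0, 400)),   # anti-VEGF in year 2
      raw_drug("r2", "BEV01", idx),
      raw_drug("r2", "DEX01", idx + 500),         # steroid only in year 2
      raw_drug("r3", "BEV01", idx)),              # nothing in year 2
    condition_occurrence = raw_cond(c("r1", "r2", "r3"), "RVO01", idx + 10),
    observation_period = raw_obs(c("r1", "r2", "r3"), idx, idx + 800))
  b <- build_cohort(t)
  pb <- persistence_breakdown(b$cohort, t)
  n_of <- function(cls) pb$n[pb$era == "P3" & pb$first_drug_class ==
                               "anti_VEGF" & pb$year2_class == cls]
  expect_equal(n_of("anti_VEGF_only"), 1L)
  expect_equal(n_of("steroid_only"), 1L)
  expect_equal(n_of("none"), 1L)
  expect_equal(n_of("both"), 0L)
  expect_equal(sum(pb$n), 3L)
})

test_that("a simulated Poisson year-1 rate is recovered by the ALL-row mean", {
  lambda <- 2.5
  cfg <- simulation_config(
    n_patients = 1500, seed = 306,
    first_line_probs = matrix(rep(c(1, 0, 0, 0, 0), 3), nrow = 3,
                              byrow = TRUE,
                              dimnames = list(c("P1", "P2", "P3"),
                                              drug_ingredients()$ingredient)),
    switch_prob = 0,
    year1_rate = c(bevacizumab = lambda, ranibizumab = 1, aflibercept = 1,
                   triamcinolone = 1, dexamethasone = 1),
    exclusion_dx_prob = 0)
  sim <- simulate_cdm(cfg)
  b <- build_cohort(sim$tables)
  it <- intensity_table(b$cohort, sim$tables,
                        intensity_config("min_2y_followup"))
  yr1 <- it[it$stratum == "all" & it$drug == "ALL" & it$year_index == 1, ]
  pooled <- sum(yr1$total) / sum(yr1$n)
  expect_lt(abs(pooled - lambda), 3 * sqrt(lambda / sum(yr1$n)))
})
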