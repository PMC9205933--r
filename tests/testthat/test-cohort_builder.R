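test_that("era assignment follows the anti-VEGF introduction boundaries", {
  cfg <- cohort_config()
  expect_equal(assign_era(as.Date("2004-05-01"), cfg), "P1")
  expect_equal(assign_era(as.Date("2005-12-31"), cfg), "P1")
  expect_equal(assign_era(as.Date("2006-01-01"), cfg), "P2")
  expect_equal(assign_era(as.Date("2011-12-31"), cfg), "P2")
  expect_equal(assign_era(as.Date("2012-01-01"), cfg), "P3")
  expect_equal(assign_era(as.Date("2018-12-31"), cfg), "P3")
  expect_error(assign_era(as.Date("2002-12-31"), cfg), "outside all eras")
})

test_that("era bounds must partition the study period", {
  eb <- default_era_bounds()
  eb$start[2] <- as.Date("2006-01-02")  # gap after P1
  expect_error(cohort_config(era_bounds = eb), "partition")
})

test_that("a patient with an in-window diagnosis and no exclusions is included", {
  t <- one_patient_tables()  # drug 2013-03-01, RVO dx 2013-06-01
  b <- build_cohort(t)
  expect_equal(nrow(b$cohort), 1)
  expect_equal(b$cohort$era, "P3")
  expect_equal(b$cohort$first_drug, "bevacizumab")
  expect_equal(b$cohort$index_date, as.Date("2013-03-01"))
  expect_equal(b$cohort$followup_days, 730L)
})

test_that("the diagnosis window is half-open at 180 days", {
  mk <- function(dx_day) {
    cdm_tables(person = raw_person("p"),
               drug_exposure = raw_drug("p", "BEV01", "2013-03-01"),
               condition_occurrence =
                 raw_cond("p", "RVO01", as.Date("2013-03-01") + dx_day),
               observation_period = raw_obs("p", "2013-03-01", "2014-12-01"))
  }
  expect_equal(nrow(build_cohort(mk(179))$cohort), 1)  # last day inside
  expect_equal(nrow(build_cohort(mk(180))$cohort), 0)  # boundary outside
  expect_equal(nrow(build_cohort(mk(198))$cohort), 0)  # day 198, as is
  expect_equal(nrow(build_cohort(mk(-1))$cohort), 0)   # pre-index dx only
})

test_that("exclusion diagnoses disqualify according to the lookback mode", {
  mk <- function(excl_date) {
    cdm_tables(person = raw_person("p"),
               drug_exposure = raw_drug("p", "BEV01", "2013-03-01"),
               condition_occurrence = dplyr::bind_rows(
                 raw_cond("p", "RVO01", "2013-04-01"),
                 raw_cond("p", "AMD01", excl_date)),
               observation_period = raw_obs("p", "2010-01-01", "2014-12-01"))
  }
  # any_time: an old AMD record disqualifies
  expect_equal(nrow(build_cohort(mk("2010-01-01"))$cohort), 0)
  # ... and so does a post-index one
  expect_equal(nrow(build_cohort(mk("2013-08-01"))$cohort), 0)
  # pre_index_only: the post-index record no longer disqualifies
  cfg <- cohort_config(exclusion_lookback = "pre_index_only")
  expect_equal(nrow(build_cohort(mk("2013-08-01"), cfg)$cohort), 1)
  expect_equal(nrow(build_cohort(mk("2010-01-01"), cfg)$cohort), 0)
})

test_that("attrition is monotone and ends at the cohort size", {
  b <- build_cohort(fixture_cdm())
  expect_true(all(diff(b$attrition$n_remaining) <= 0))
  expect_equal(b$attrition$n_remaining[nrow(b$attrition)], nrow(b$cohort))
  expect_equal(b$attrition$n_remaining, c(8L, 8L, 7L, 6L, 6L))
})

test_that("every cohort member has a target-drug exposure on the index date", {
  t <- fixture_cdm()
  b <- suppressMessages(build_cohort(t))
  on_index <- dplyr::inner_join(
    t$drug_exposure,
    dplyr::select(b$cohort, person_id, index_date, first_drug),
    by = "person_id")
  on_index <- on_index[on_index$exposure_date == on_index$index_date &
                         on_index$ingredient == on_index$first_drug, ]
  expect_setequal(on_index$person_id, b$cohort$person_id)
})

test_that("a table without RVO diagnoses yields an empty cohort", {
  t <- cdm_tables(person = raw_person("p"),
                  drug_exposure = raw_drug("p", "BEV01", "2013-03-01"),
                  observation_period = raw_obs("p", "2013-03-01", "2014-12-01"))
  b <- build_cohort(t)
  expect_equal(nrow(b$cohort), 0)
  expect_true(all(diff(b$attrition$n_remaining) <= 0))
})

test_that("the cohort is invariant under permutation of input row order", {
  raw <- rvopathways:::fixture_raw_tables()
  set.seed(42)
  shuffled <- lapply(raw, function(df) df[sample(nrow(df)), ])
  t1 <- fixture_cdm()
  t2 <- cdm_tables(shuffled$person, shuffled$drug_exposure,
                   shuffled$condition_occurrence,
                   shuffled$observation_period)
  b1 <- suppressMessages(build_cohort(t1))
  b2 <- suppressMessages(build_cohort(t2))
  expect_equal(b2$cohort, b1$cohort)
  expect_equal(b2$attrition, b1$attrition)
})

test_that("same-day two-drug starts break ties by canonical ingredient order", {
  t <- cdm_tables(person = raw_person("p"),
                  drug_exposure = dplyr::bind_rows(
                    raw_drug("p", "TRI01", "2013-03-01"),
                    raw_drug("p", "BEV01", "2013-03-01")),
                  condition_occurrence = raw_cond("p", "RVO01", "2013-04-01"),
                  observation_period = raw_obs("p", "2013-03-01", "2014-12-01"))
  expect_message(b <- build_cohort(t), "two or more drugs")
  expect_equal(b$cohort$first_drug, "bevacizumab")
  expect_equal(b$cohort$first_drug_class, "anti_VEGF")
})

test_that("index dates outside the study period are rejected at step 2", {
  t <- cdm_tables(person = raw_person("p"),
                  drug_exposure = raw_drug("p", "BEV01", "2002-06-01"),
                  condition_occurrence = raw_cond("p", "RVO01", "2002-07-01"),
                  observation_period = raw_obs("p", "2002-06-01", "2004-12-01"))
  b <- build_cohort(t)
  expect_equal(nrow(b$cohort), 0)
  expect_equal(b$attrition$n_remaining[2], 0L)
})

test_that("a missing observation period is imputed or rejected per config", {
  t <- cdm_tables(person = raw_person("p"),
                  drug_exposure = dplyr::bind_rows(
                    raw_drug("p", "BEV01", "2013-03-01"),
                    raw_drug("p", "BEV01", "2013-09-01")),
                  condition_occurrence = raw_cond("p", "RVO01", "2013-04-01"))
  expect_warning(b <- build_cohort(t), "no observation period")
  # imputed period spans first to last event: 2013-03-01 .. 2013-09-01
  expect_equal(b$cohort$followup_days, 184L)
  expect_error(
    suppressWarnings(build_cohort(
      t, cohort_config(missing_observation_period = "strict"))),
    "no observation period")
})
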