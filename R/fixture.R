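# Packaged 8-patient fixture ------------------------------------------------
#
# Hand-designed to exercise every inclusion/exclusion rule and both
# follow-up regimes:
#   f1  P3  bevacizumab only, followed 800 d (year-2 denominator member)
#   f2  --  RVO diagnosis on day 198: fails the 180-day window
#   f3  --  carries an exclusion diagnosis (exudative AMD): excluded
#   f4  P3  followed only 200 d (drops out of year-2 denominators)
#   f5  P2  bev > triam > bev > dex: re-prescription collapse (3 lines)
#   f6  P2  bevacizumab and triamcinolone on the same index day (tie-break)
#   f7  P1  triamcinolone only, followed 800 d
#   f8  P3  aflibercept then ranibizumab, followed 750 d
# Six of the eight qualify for the cohort; all five drugs appear.

fixture_raw_tables <- function() {
  d <- as.Date
  person <- tibble::tibble(
    person_id = paste0("f", 1:8),
    birth_year = c(1950L, 1948L, 1962L, 1955L, 1941L, 1958L, 1939L, 1960L),
    sex = c("F", "M", "F", "M", "F", "F", "M", "M"),
    site_id = c(rep("S1", 4), rep("S2", 4)))

  exp_row <- function(pid, code, vocab, date) {
    tibble::tibble(person_id = pid, drug_code = code, vocabulary = vocab,
                   exposure_date = d(date))
  }
  rx <- function(pid, code, index, day) {
    exp_row(pid, code, "demo-rx", as.character(d(index) + day))
  }
  drug_exposure <- dplyr::bind_rows(
    rx("f1", "BEV01", "2013-03-01", 0), rx("f1", "BEV02", "2013-03-01", 30),
    rx("f1", "BEV01", "2013-03-01", 60), rx("f1", "BEV01", "2013-03-01", 400),
    rx("f2", "BEV01", "2013-03-01", 0),
    rx("f3", "BEV01", "2013-05-01", 0),
    rx("f4", "BEV01", "2014-06-01", 0), rx("f4", "BEV01", "2014-06-01", 45),
    rx("f5", "BEV01", "2008-02-01", 0), rx("f5", "TRI01", "2008-02-01", 60),
    rx("f5", "BEV01", "2008-02-01", 120), rx("f5", "DEX01", "2008-02-01", 200),
    rx("f5", "DEX01", "2008-02-01", 500),
    rx("f6", "BEV01", "2010-05-01", 0), rx("f6", "TRI01", "2010-05-01", 0),
    rx("f6", "TRI02", "2010-05-01", 90),
    rx("f7", "TRI01", "2004-03-01", 0), rx("f7", "TRI01", "2004-03-01", 90),
    rx("f7", "TRI01", "2004-03-01", 200), rx("f7", "TRI02", "2004-03-01", 400),
    rx("f8", "AFL01", "2015-01-10", 0), rx("f8", "AFL01", "2015-01-10", 30),
    rx("f8", "RAN01", "2015-01-10", 100), rx("f8", "RAN01", "2015-01-10", 380))

  dx <- function(pid, code, index, day) {
    tibble::tibble(person_id = pid, condition_code = code,
                   vocabulary = "demo-dx",
                   condition_date = d(index) + day)
  }
  condition_occurrence <- dplyr::bind_rows(
    dx("f1", "RVO01", "2013-03-01", 31),
    dx("f2", "RVO01", "2013-03-01", 198),   # day 198 >= 180: outside window
    dx("f3", "RVO02", "2013-05-01", 31),
    dx("f3", "AMD01", "2010-01-01", 0),     # exclusion diagnosis
    dx("f4", "RVO03", "2014-06-01", 10),
    dx("f5", "RVO01", "2008-02-01", 20),
    dx("f6", "RVO02", "2010-05-01", 5),
    dx("f7", "RVO01", "2004-03-01", 15),
    dx("f8", "RVO03", "2015-01-10", 40))

  op <- function(pid, start, days) {
    tibble::tibble(person_id = pid, start_date = d(start),
                   end_date = d(start) + days)
  }
  observation_period <- dplyr::bind_rows(
    op("f1", "2013-03-01", 800), op("f2", "2013-03-01", 400),
    op("f3", "2013-05-01", 400), op("f4", "2014-06-01", 200),
    op("f5", "2008-02-01", 900), op("f6", "2010-05-01", 400),
    op("f7", "2004-03-01", 800), op("f8", "2015-01-10", 750))

  list(person = person, drug_exposure = drug_exposure,
       condition_occurrence = condition_occurrence,
       observation_period = observation_period)
}

#' Packaged 8-patient fixture
#'
#' `fixture_cdm()` returns the fixture as loaded `cdm_tables`;
#' `make_fixture()` writes it as the four CSV files plus the default concept
#' registry JSON, so a written fixture directory is a complete, self-contained
#' input for [run_pipeline()].
#'
#' The fixture covers all three analysis eras and all five drugs, and
#' contains one patient failing the 180-day diagnosis window, one with an
#' exclusion diagnosis, one followed under a year, two followed over two
#' years, one re-prescription pattern exercising the line-collapse rule and
#' one same-day two-drug start; six of its eight patients qualify for the
#' cohort.
#'
#' @param dir Output directory for `make_fixture()` (created if needed).
#' @return `fixture_cdm()`: a `cdm_tables`. `make_fixture()`: named vector of
#'   written paths, invisibly.
#' @export
fixture_cdm <- function() {
  raw <- fixture_raw_tables()
  cdm_tables(raw$person, raw$drug_exposure, raw$condition_occurrence,
             raw$observation_period)
}

#' @rdname fixture_cdm
#' @export
make_fixture <- function(dir) {
  tables <- fixture_cdm()
  paths <- write_cdm_tables(tables, dir)
  reg_path <- file.path(dir, "concept_registry.json")
  write_concept_registry(default_concept_registry(), reg_path)
  invisible(c(paths, registry = reg_path))
}
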