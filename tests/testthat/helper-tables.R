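# small builders for raw-form tables used across tests

raw_person <- function(ids, site = "S1", birth_year = 1950L) {
  tibble::tibble(person_id = ids, birth_year = birth_year,
                 sex = "F", site_id = site)
}

raw_drug <- function(pid, code, date, vocabulary = "demo-rx") {
  tibble::tibble(person_id = pid, drug_code = code, vocabulary = vocabulary,
                 exposure_date = as.Date(date))
}

raw_cond <- function(pid, code, date, vocabulary = "demo-dx") {
  tibble::tibble(person_id = pid, condition_code = code,
                 vocabulary = vocabulary, condition_date = as.Date(date))
}

raw_obs <- function(pid, start, end) {
  tibble::tibble(person_id = pid, start_date = as.Date(start),
                 end_date = as.Date(end))
}

# one clean patient: bevacizumab index 2013-03-01, RVO dx a month later
one_patient_tables <- function(pid = "p1") {
  cdm_tables(
    person = raw_person(pid),
    drug_exposure = raw_drug(pid, "BEV01", "2013-03-01"),
    condition_occurrence = raw_cond(pid, "RVO01", "2013-06-01"),
    observation_period = raw_obs(pid, "2013-03-01", "2015-03-01"))
}

# write raw tables to a directory in the on-disk CSV dialect
write_raw_dir <- function(dir, person, drug_exposure = NULL,
                          condition_occurrence = NULL,
                          observation_period = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  empty <- list(
    drug_exposure = raw_drug(character(0), character(0), character(0)),
    condition_occurrence = raw_cond(character(0), character(0), character(0)),
    observation_period = raw_obs(character(0), character(0), character(0)))
  tabs <- list(person = person,
               drug_exposure = drug_exposure %||% empty$drug_exposure,
               condition_occurrence =
                 condition_occurrence %||% empty$condition_occurrence,
               observation_period =
                 observation_period %||% empty$observation_period)
  for (nm in names(tabs)) {
    df <- as.data.frame(tabs[[nm]])
    for (dc in names(df)) {
      if (inherits(df[[dc]], "Date")) df[[dc]] <- format(df[[dc]], "%Y-%m-%d")
    }
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  dir
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent stable-dedup oracle for line derivation: explicit seen-set loop
dedup_oracle <- function(x) {
  seen <- character(0)
  for (d in x) if (!d %in% seen) seen <- c(seen, d)
  seen
}

# recursive sunburst conservation check: every parent equals the sum of its
# children (extensions + stop leaf)
check_sunburst_conservation <- function(node) {
  if (is.null(node$children)) return(invisible(TRUE))
  kids <- sum(vapply(node$children, function(k) k$value, numeric(1)))
  expect_equal(kids, node$value)
  for (k in node$children) check_sunburst_conservation(k)
  invisible(TRUE)
}
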