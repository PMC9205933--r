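# Cohort phenotyping --------------------------------------------------------

#' Cohort configuration
#'
#' Settings for the phenotype algorithm: study period, the post-index
#' diagnosis inclusion window, analysis-era boundaries and exclusion-lookback
#' semantics.
#'
#' The default eras follow the introduction of anti-VEGF therapy:
#' `P1` 2003-01-01..2005-12-31 (pre anti-VEGF), `P2` 2006-01-01..2011-12-31
#' (off-label bevacizumab era), `P3` 2012-01-01..2018-12-31 (on-label
#' anti-VEGF era). Era bounds must partition the study period.
#'
#' @param study_start,study_end Study period bounds (dates or ISO strings).
#' @param inclusion_window_days Length of the half-open post-index window
#'   `[index, index + window)` in which a qualifying RVO diagnosis must fall.
#' @param era_bounds Data frame with columns `era`, `start`, `end`.
#' @param exclusion_lookback `"any_time"`: any record of an exclusion
#'   diagnosis disqualifies; `"pre_index_only"`: only records dated on or
#'   before the index date disqualify.
#' @param missing_observation_period `"impute"` (default): a person with
#'   events but no observation period gets one spanning first to last event,
#'   with a warning; `"strict"`: such a person aborts the run.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(study_start = "2003-01-01",
                          study_end = "2018-12-31",
                          inclusion_window_days = 180L,
                          era_bounds = default_era_bounds(),
                          exclusion_lookback = c("any_time", "pre_index_only"),
                          missing_observation_period = c("impute", "strict")) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  exclusion_lookback <- match.arg(exclusion_lookback)
  missing_observation_period <- match.arg(missing_observation_period)
  stopifnot(study_start < study_end, inclusion_window_days > 0)
  era_bounds <- tibble::as_tibble(era_bounds)
  stopifnot(all(c("era", "start", "end") %in% names(era_bounds)))
  era_bounds$start <- as.Date(era_bounds$start)
  era_bounds$end <- as.Date(era_bounds$end)
  era_bounds <- dplyr::arrange(era_bounds, .data$start)
  if (era_bounds$start[1] != study_start ||
      era_bounds$end[nrow(era_bounds)] != study_end ||
      (nrow(era_bounds) > 1 &&
       any(era_bounds$start[-1] != era_bounds$end[-nrow(era_bounds)] + 1L))) {
    stop("era_bounds must partition [study_start, study_end] with no gaps",
         call. = FALSE)
  }
  structure(list(study_start = study_start, study_end = study_end,
                 inclusion_window_days = as.integer(inclusion_window_days),
                 era_bounds = era_bounds,
                 exclusion_lookback = exclusion_lookback,
                 missing_observation_period = missing_observation_period),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_era_bounds <- function() {
  tibble::tibble(
    era = c("P1", "P2", "P3"),
    start = as.Date(c("2003-01-01", "2006-01-01", "2012-01-01")),
    end = as.Date(c("2005-12-31", "2011-12-31", "2018-12-31"))
  )
}

#' Assign analysis eras to index dates
#'
#' @param index_date Vector of dates.
#' @param config A [cohort_config()].
#' @return Character vector of era labels.
#' @export
#' @examples
#' assign_era(as.Date(c("2004-05-01", "2011-12-31", "2012-01-01")),
#'            cohort_config())
assign_era <- function(index_date, config = cohort_config()) {
  index_date <- as.Date(index_date)
  eb <- config$era_bounds
  idx <- vapply(as.integer(index_date), function(d) {
    w <- which(d >= as.integer(eb$start) & d <= as.integer(eb$end))
    if (length(w) == 0) NA_integer_ else w[1]
  }, integer(1))
  if (anyNA(idx[!is.na(index_date)])) {
    bad <- index_date[is.na(idx) & !is.na(index_date)]
    stop("configuration error: date(s) outside all eras: ",
         paste(utils::head(format(bad), 3), collapse = ", "), call. = FALSE)
  }
  eb$era[idx]
}

#' Build the treatment cohort
#'
#' Applies the phenotype algorithm in order: (1) the first exposure to any of
#' the five target drugs defines the index date (same-day ties broken by the
#' canonical ingredient order, and logged); (2) the index date must fall
#' within the study period; (3) at least one RVO-set diagnosis must fall in
#' the half-open window `[index, index + inclusion_window_days)`; (4) no
#' exclusion-set diagnosis per `exclusion_lookback`; (5) the era is assigned
#' from the index date. Follow-up is `observation_period.end - index` in
#' whole days (clamped at 0 if the period ends before index, which is
#' reported).
#'
#' @param tables A `cdm_tables` object.
#' @param config A [cohort_config()].
#' @return A list with `cohort` (tibble: `person_id`, `site_id`,
#'   `index_date`, `first_drug`, `first_drug_class`, `era`, `followup_days`)
#'   and `attrition` (tibble: `step`, `n_remaining`, non-increasing).
#' @export
build_cohort <- function(tables, config = cohort_config()) {
  stopifnot(inherits(tables, "cdm_tables"), inherits(config, "cohort_config"))
  drug <- tables$drug_exposure
  cond <- tables$condition_occurrence
  obs <- tables$observation_period

  attrition <- tibble::tibble(step = character(), n_remaining = integer())
  record <- function(step, n) {
    attrition <<- dplyr::bind_rows(attrition,
                                   tibble::tibble(step = step,
                                                  n_remaining = as.integer(n)))
  }

  # step 1: index date = first target-drug exposure; tie-break by ingredient
  first_exp <- drug |>
    dplyr::arrange(.data$person_id, .data$exposure_date,
                   ingredient_rank(.data$ingredient)) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
    dplyr::select(person_id = "person_id", index_date = "exposure_date",
                  first_drug = "ingredient", first_drug_class = "drug_class")
  record("persons with target drug exposure", nrow(first_exp))

  same_day_ties <- drug |>
    dplyr::inner_join(first_exp, by = "person_id") |>
    dplyr::filter(.data$exposure_date == .data$index_date) |>
    dplyr::distinct(.data$person_id, .data$ingredient) |>
    dplyr::count(.data$person_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(same_day_ties) > 0) {
    message(nrow(same_day_ties),
            " person(s) started two or more drugs on the index date; ",
            "first drug chosen by canonical ingredient order")
  }

  # step 2: index within study period
  cand <- dplyr::filter(first_exp,
                        .data$index_date >= config$study_start,
                        .data$index_date <= config$study_end)
  record("index date within study period", nrow(cand))

  # step 3: RVO diagnosis within [index, index + window)
  rvo <- dplyr::filter(cond, .data$concept_set_id == "rvo")
  has_rvo <- cand |>
    dplyr::inner_join(rvo, by = "person_id", relationship = "one-to-many") |>
    dplyr::filter(.data$condition_date >= .data$index_date,
                  .data$condition_date < .data$index_date +
                    config$inclusion_window_days) |>
    dplyr::distinct(.data$person_id)
  cand <- dplyr::semi_join(cand, has_rvo, by = "person_id")
  record(sprintf("RVO diagnosis within %d days of index",
                 config$inclusion_window_days), nrow(cand))

  # step 4: no exclusion-set diagnosis
  excl <- dplyr::filter(cond, .data$concept_set_id == "exclusion")
  if (config$exclusion_lookback == "pre_index_only") {
    excl <- excl |>
      dplyr::inner_join(dplyr::select(cand, "person_id", "index_date"),
                        by = "person_id", relationship = "many-to-one") |>
      dplyr::filter(.data$condition_date <= .data$index_date)
  }
  cand <- dplyr::anti_join(cand, excl, by = "person_id")
  record("no exclusion diagnosis", nrow(cand))

  # step 5: era + follow-up
  cand$era <- assign_era(cand$index_date, config)

  no_obs <- setdiff(cand$person_id, obs$person_id)
  if (length(no_obs) > 0) {
    if (config$missing_observation_period == "strict") {
      stop("person(s) with drug exposure but no observation period: ",
           paste(utils::head(no_obs, 5), collapse = ", "), call. = FALSE)
    }
    warning(length(no_obs), " person(s) had no observation period; ",
            "imputed as [first event, last event]", call. = FALSE)
    events <- dplyr::bind_rows(
      dplyr::select(drug, "person_id", date = "exposure_date"),
      dplyr::select(cond, "person_id", date = "condition_date")
    ) |>
      dplyr::filter(.data$person_id %in% no_obs) |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(start_date = min(.data$date),
                       end_date = max(.data$date), .groups = "drop")
    obs <- dplyr::bind_rows(obs, events)
  }

  cohort <- cand |>
    dplyr::left_join(dplyr::select(obs, "person_id", "end_date"),
                     by = "person_id") |>
    dplyr::mutate(followup_days = as.integer(.data$end_date - .data$index_date))
  if (any(cohort$followup_days < 0)) {
    warning(sum(cohort$followup_days < 0),
            " person(s) had an observation period ending before index; ",
            "follow-up clamped to 0", call. = FALSE)
    cohort$followup_days <- pmax(cohort$followup_days, 0L)
  }
  cohort <- cohort |>
    dplyr::left_join(dplyr::select(tables$person, "person_id", "site_id"),
                     by = "person_id") |>
    dplyr::select("person_id", "site_id", "index_date", "first_drug",
                  "first_drug_class", "era", "followup_days") |>
    dplyr::arrange(.data$person_id)
  record("final cohort", nrow(cohort))

  list(cohort = cohort, attrition = attrition)
}

#' Target-drug exposures of cohort members from the index date onward
#'
#' Joins the drug-exposure table to the cohort, keeps exposures dated on or
#' after each member's index date, and adds `day` (days since index). This is
#' the input both pathway mining and intensity calculation consume.
#'
#' @param tables A `cdm_tables` object.
#' @param cohort The cohort tibble from [build_cohort()].
#' @return Tibble: `person_id`, `ingredient`, `drug_class`, `exposure_date`,
#'   `day`, ordered by person, day and canonical ingredient order.
#' @export
cohort_exposures <- function(tables, cohort) {
  tables$drug_exposure |>
    dplyr::inner_join(dplyr::select(cohort, "person_id", "index_date"),
                      by = "person_id", relationship = "many-to-one") |>
    dplyr::filter(.data$exposure_date >= .data$index_date) |>
    dplyr::mutate(day = as.integer(.data$exposure_date - .data$index_date)) |>
    dplyr::arrange(.data$person_id, .data$day,
                   ingredient_rank(.data$ingredient)) |>
    dplyr::select("person_id", "ingredient", "drug_class", "exposure_date",
                  "day")
}
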