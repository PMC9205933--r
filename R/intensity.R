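# Treatment intensity -------------------------------------------------------

#' Post-index year windows
#'
#' Year `k` after index is the half-open window
#' `[index + 365*(k-1), index + 365*k)` in days; day 365 belongs to year 2.
#' Year length is fixed at 365 days (no leap adjustment) so windows are
#' deterministic.
#'
#' @param year_index 1 or 2.
#' @return Integer vector `c(start_day, end_day)` (end exclusive).
#' @export
year_window <- function(year_index) {
  stopifnot(year_index %in% c(1L, 2L))
  c(365L * (year_index - 1L), 365L * year_index)
}

#' Count one person's injections in a year window
#'
#' @param exposures Tibble of one person's post-index exposures with columns
#'   `ingredient` and `day` (days since index), e.g. one group of
#'   [cohort_exposures()].
#' @param drug Ingredient name, or `"ALL"` for any of the five target drugs.
#' @param year_index 1 or 2.
#' @param same_day_dedup Count same person/drug/date duplicates once
#'   (default `TRUE`; bilateral same-day injections are indistinguishable
#'   without laterality).
#' @return Integer count.
#' @export
#' @examples
#' ex <- tibble::tibble(ingredient = "bevacizumab", day = c(0L, 30L, 364L, 365L))
#' count_injections(ex, "bevacizumab", 1)  # 3
#' count_injections(ex, "bevacizumab", 2)  # 1
count_injections <- function(exposures, drug = "ALL", year_index = 1,
                             same_day_dedup = TRUE) {
  w <- year_window(year_index)
  keep <- exposures$day >= w[1] & exposures$day < w[2]
  if (!identical(drug, "ALL")) keep <- keep & exposures$ingredient == drug
  ex <- exposures[keep, c("ingredient", "day")]
  if (same_day_dedup) ex <- dplyr::distinct(ex)
  nrow(ex)
}

#' Intensity configuration
#'
#' @param cohort_scope `"all_patients"` (year-1 column over everyone, year-2
#'   column over members followed at least 365 days) or `"min_2y_followup"`
#'   (both columns restricted to members followed at least 730 days, the
#'   sensitivity analysis).
#' @param drug_row_denominator For per-drug rows: `"received_in_year1"`
#'   (denominator = stratum members with at least one year-1 injection of the
#'   drug; the year-2 column restricts that same set by follow-up) or
#'   `"all_in_stratum"` (same denominators as the ALL row).
#' @param same_day_dedup Count same person/drug/date duplicates once.
#' @return An `intensity_config` list.
#' @export
intensity_config <- function(cohort_scope = c("all_patients", "min_2y_followup"),
                             drug_row_denominator = c("received_in_year1",
                                                      "all_in_stratum"),
                             same_day_dedup = TRUE) {
  structure(list(cohort_scope = match.arg(cohort_scope),
                 drug_row_denominator = match.arg(drug_row_denominator),
                 same_day_dedup = isTRUE(same_day_dedup)),
            class = "intensity_config")
}

# per (person, drug, year) deduplicated injection counts for cohort members
person_drug_year_counts <- function(cohort, exposures, same_day_dedup = TRUE) {
  ex <- dplyr::semi_join(exposures, cohort, by = "person_id")
  ex <- dplyr::filter(ex, .data$day < 730L)
  if (same_day_dedup) {
    ex <- dplyr::distinct(ex, .data$person_id, .data$ingredient, .data$day)
  }
  ex |>
    dplyr::mutate(year_index = ifelse(.data$day < 365L, 1L, 2L)) |>
    dplyr::count(.data$person_id, .data$ingredient, .data$year_index,
                 name = "injections")
}

#' Treatment-intensity table
#'
#' Average number of intravitreal injections per patient in years 1 and 2
#' after index, by era, first-drug-class stratum and drug. The ALL row of
#' each era/stratum uses all (in-scope) stratum members as the year-1
#' denominator and members followed at least 365 days as the year-2
#' denominator; per-drug rows follow `drug_row_denominator`. Cells with an
#' empty denominator are emitted with `n = 0` and `mean = NA`.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param exposures [cohort_exposures()] tibble (or the `cdm_tables`).
#' @param config An [intensity_config()].
#' @return Tibble `era`, `stratum` (`anti_VEGF_first`, `steroid_first`,
#'   `all`), `drug` (`ALL` or ingredient), `year_index`, `n`, `total`,
#'   `mean`.
#' @export
intensity_table <- function(cohort, exposures, config = intensity_config()) {
  stopifnot(inherits(config, "intensity_config"))
  if (inherits(exposures, "cdm_tables")) {
    exposures <- cohort_exposures(exposures, cohort)
  }
  if (config$cohort_scope == "min_2y_followup") {
    cohort <- dplyr::filter(cohort, .data$followup_days >= 730L)
  }
  eras <- sort(unique(cohort$era))
  strata <- c("anti_VEGF_first", "steroid_first", "all")
  drugs <- c("ALL", .ingredients)

  counts <- person_drug_year_counts(cohort, exposures, config$same_day_dedup)

  stratum_members <- function(era, stratum) {
    m <- cohort[cohort$era == era, ]
    if (stratum == "anti_VEGF_first") m <- m[m$first_drug_class == "anti_VEGF", ]
    if (stratum == "steroid_first") m <- m[m$first_drug_class == "steroid", ]
    m
  }

  grid <- expand.grid(era = eras, stratum = strata, drug = drugs,
                      year_index = 1:2, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) {
    return(tibble::tibble(era = character(), stratum = character(),
                          drug = character(), year_index = integer(),
                          n = integer(), total = integer(), mean = numeric()))
  }
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    members <- stratum_members(g$era, g$stratum)
    if (g$drug == "ALL" || config$drug_row_denominator == "all_in_stratum") {
      denom_ids <- members$person_id
    } else {
      got_yr1 <- counts$person_id[counts$ingredient == g$drug &
                                    counts$year_index == 1L]
      denom_ids <- intersect(members$person_id, got_yr1)
    }
    if (g$year_index == 2L && config$cohort_scope == "all_patients") {
      ok <- members$person_id[members$followup_days >= 365L]
      denom_ids <- intersect(denom_ids, ok)
    }
    cc <- counts[counts$person_id %in% denom_ids &
                   counts$year_index == g$year_index, ]
    if (g$drug != "ALL") cc <- cc[cc$ingredient == g$drug, ]
    n <- length(denom_ids)
    total <- sum(cc$injections)
    tibble::tibble(era = g$era, stratum = g$stratum, drug = g$drug,
                   year_index = as.integer(g$year_index), n = as.integer(n),
                   total = as.integer(total),
                   mean = if (n == 0) NA_real_ else total / n)
  })
  dplyr::bind_rows(cells) |>
    dplyr::arrange(.data$era, match(.data$stratum, strata),
                   match(.data$drug, drugs), .data$year_index)
}

#' Second-year treatment-class persistence
#'
#' Classifies each member followed at least 365 days by the drug classes
#' received in year 2: `anti_VEGF_only`, `steroid_only`, `both` or `none`,
#' cross-tabulated by era and first-drug class.
#'
#' @inheritParams intensity_table
#' @param same_day_dedup Count same person/drug/date duplicates once.
#' @return Tibble `era`, `first_drug_class`, `year2_class`, `n` (complete
#'   over all combinations present in the cohort's eras).
#' @export
persistence_breakdown <- function(cohort, exposures, same_day_dedup = TRUE) {
  if (inherits(exposures, "cdm_tables")) {
    exposures <- cohort_exposures(exposures, cohort)
  }
  eligible <- dplyr::filter(cohort, .data$followup_days >= 365L)
  counts <- person_drug_year_counts(eligible, exposures, same_day_dedup)
  yr2 <- counts |>
    dplyr::filter(.data$year_index == 2L) |>
    dplyr::mutate(drug_class = drug_class_of(.data$ingredient)) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(got_vegf = any(.data$drug_class == "anti_VEGF"),
                     got_steroid = any(.data$drug_class == "steroid"),
                     .groups = "drop")
  classified <- eligible |>
    dplyr::left_join(yr2, by = "person_id") |>
    dplyr::mutate(
      got_vegf = dplyr::coalesce(.data$got_vegf, FALSE),
      got_steroid = dplyr::coalesce(.data$got_steroid, FALSE),
      year2_class = dplyr::case_when(
        .data$got_vegf & .data$got_steroid ~ "both",
        .data$got_vegf ~ "anti_VEGF_only",
        .data$got_steroid ~ "steroid_only",
        TRUE ~ "none"))
  classified |>
    dplyr::count(.data$era, .data$first_drug_class, .data$year2_class,
                 name = "n") |>
    tidyr::complete(era = sort(unique(cohort$era)),
                    first_drug_class = c("anti_VEGF", "steroid"),
                    year2_class = c("anti_VEGF_only", "steroid_only",
                                    "both", "none"),
                    fill = list(n = 0L)) |>
    dplyr::arrange(.data$era, .data$first_drug_class, .data$year2_class)
}
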