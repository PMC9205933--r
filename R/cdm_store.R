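# Minimal CDM-shaped table store --------------------------------------------
#
# Four flat tables mirror the OMOP CDM tables the analysis needs:
#   person(person_id, birth_year, sex, site_id)
#   drug_exposure(person_id, drug_code, vocabulary, exposure_date)
#   condition_occurrence(person_id, condition_code, vocabulary, condition_date)
#   observation_period(person_id, start_date, end_date)
# Files are UTF-8 CSV with a header row and ISO-8601 dates.

.cdm_schemas <- list(
  person = c("person_id", "birth_year", "sex", "site_id"),
  drug_exposure = c("person_id", "drug_code", "vocabulary", "exposure_date"),
  condition_occurrence = c("person_id", "condition_code", "vocabulary",
                           "condition_date"),
  observation_period = c("person_id", "start_date", "end_date")
)

.cdm_files <- c(person = "person.csv",
                drug_exposure = "drug_exposure.csv",
                condition_occurrence = "condition_occurrence.csv",
                observation_period = "observation_period.csv")

.date_min <- as.Date("1900-01-01")
.date_max <- as.Date("2100-01-01")

parse_iso_dates <- function(x, file, column) {
  x <- as.character(x)
  d <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  wellformed <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d[wellformed] <- as.Date(x[wellformed], format = "%Y-%m-%d")
  bad <- which(is.na(d) | d < .date_min | d > .date_max)
  if (length(bad) > 0) {
    # +1 for the header row so the number matches the physical file line
    stop(sprintf("unparseable or out-of-range date in %s, column %s, line %d: '%s'",
                 file, column, bad[1] + 1L, x[bad[1]]), call. = FALSE)
  }
  d
}

check_columns <- function(df, table) {
  missing <- setdiff(.cdm_schemas[[table]], names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error in %s: missing required column(s) %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[, .cdm_schemas[[table]]]
}

empty_raw_tables <- function() {
  list(
    person = tibble::tibble(person_id = character(), birth_year = integer(),
                            sex = character(), site_id = character()),
    drug_exposure = tibble::tibble(person_id = character(),
                                   drug_code = character(),
                                   vocabulary = character(),
                                   exposure_date = as.Date(character())),
    condition_occurrence = tibble::tibble(person_id = character(),
                                          condition_code = character(),
                                          vocabulary = character(),
                                          condition_date = as.Date(character())),
    observation_period = tibble::tibble(person_id = character(),
                                        start_date = as.Date(character()),
                                        end_date = as.Date(character()))
  )
}

# Shared validation/resolution path for file loads and in-memory construction.
resolve_cdm <- function(raw, registry) {
  report <- tibble::tibble(issue = character(), n = integer())
  note <- function(issue, n) {
    if (n > 0) report <<- dplyr::bind_rows(report,
                                           tibble::tibble(issue = issue,
                                                          n = as.integer(n)))
  }

  person <- raw$person
  person$person_id <- as.character(person$person_id)
  person$birth_year <- as.integer(person$birth_year)
  if (anyDuplicated(person$person_id)) {
    dup <- unique(person$person_id[duplicated(person$person_id)])
    stop("integrity error: duplicate person_id in PERSON: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  n_bad_by <- sum(!is.na(person$birth_year) &
                    (person$birth_year < 1880 | person$birth_year > 2018))
  note("implausible_birth_year", n_bad_by)

  known <- person$person_id

  drug <- raw$drug_exposure
  drug$person_id <- as.character(drug$person_id)
  drug$drug_code <- as.character(drug$drug_code)
  drug$vocabulary <- as.character(drug$vocabulary)
  drug_map <- registry_lookup(registry, "drug")
  drug <- dplyr::left_join(drug, dplyr::rename(drug_map, ingredient = "set_id"),
                           by = c("vocabulary", "drug_code" = "code"))
  note("drug_code_unresolved", sum(is.na(drug$ingredient)))
  drug <- drug[!is.na(drug$ingredient), ]
  note("drug_exposure_unknown_person", sum(!drug$person_id %in% known))
  drug <- drug[drug$person_id %in% known, ]
  drug$drug_class <- drug_class_of(drug$ingredient)
  drug <- dplyr::arrange(drug, .data$person_id, .data$exposure_date,
                         ingredient_rank(.data$ingredient))
  drug <- drug[, c("person_id", "drug_code", "vocabulary", "ingredient",
                   "drug_class", "exposure_date")]

  cond <- raw$condition_occurrence
  cond$person_id <- as.character(cond$person_id)
  cond$condition_code <- as.character(cond$condition_code)
  cond$vocabulary <- as.character(cond$vocabulary)
  dx_map <- registry_lookup(registry, "diagnosis")
  cond <- dplyr::left_join(cond, dplyr::rename(dx_map, concept_set_id = "set_id"),
                           by = c("vocabulary", "condition_code" = "code"))
  note("condition_code_unresolved", sum(is.na(cond$concept_set_id)))
  cond$concept_set_id[is.na(cond$concept_set_id)] <- "other"
  note("condition_unknown_person", sum(!cond$person_id %in% known))
  cond <- cond[cond$person_id %in% known, ]
  cond <- dplyr::arrange(cond, .data$person_id, .data$condition_date,
                         .data$concept_set_id)
  cond <- cond[, c("person_id", "condition_code", "vocabulary",
                   "concept_set_id", "condition_date")]

  obs <- raw$observation_period
  obs$person_id <- as.character(obs$person_id)
  if (any(obs$start_date > obs$end_date)) {
    stop("observation_period has start_date after end_date", call. = FALSE)
  }
  note("observation_period_unknown_person", sum(!obs$person_id %in% known))
  obs <- obs[obs$person_id %in% known, ]
  n_before <- nrow(obs)
  # merge-on-load: one observation span per person (union over all rows)
  if (n_before > 0) {
    obs <- obs |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(start_date = min(.data$start_date),
                       end_date = max(.data$end_date), .groups = "drop") |>
      dplyr::arrange(.data$person_id)
  }
  obs <- tibble::as_tibble(obs)[, c("person_id", "start_date", "end_date")]
  note("observation_periods_merged", n_before - nrow(obs))

  structure(list(person = dplyr::arrange(tibble::as_tibble(person),
                                         .data$person_id),
                 drug_exposure = tibble::as_tibble(drug),
                 condition_occurrence = tibble::as_tibble(cond),
                 observation_period = tibble::as_tibble(obs),
                 load_report = report),
            class = "cdm_tables")
}

#' Load the four CDM-shaped tables from delimited files
#'
#' Reads `person.csv`, `drug_exposure.csv`, `condition_occurrence.csv` and
#' `observation_period.csv` from `dir` (or explicit paths), resolves raw drug
#' and condition codes against the concept registry, merges each person's
#' observation-period rows into a single span, and validates integrity.
#'
#' Drug exposures whose code is in no drug concept set are dropped and
#' counted in the load report; condition codes outside the registered
#' diagnosis sets are retained with `concept_set_id = "other"` and counted.
#'
#' @param dir Directory containing the four CSV files.
#' @param registry A `concept_registry` (default
#'   [default_concept_registry()]).
#' @param paths Optional named list/vector overriding individual file paths
#'   (names among `person`, `drug_exposure`, `condition_occurrence`,
#'   `observation_period`).
#' @return A `cdm_tables` object: a list with the four resolved tibbles and a
#'   `load_report` tibble of `(issue, n)` counts.
#' @export
load_cdm_tables <- function(dir = NULL, registry = default_concept_registry(),
                            paths = NULL) {
  files <- as.list(file.path(dir %||% ".", .cdm_files))
  names(files) <- names(.cdm_files)
  if (!is.null(paths)) files[names(paths)] <- as.list(paths)
  for (f in unlist(files)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }

  read_one <- function(table) {
    df <- utils::read.csv(files[[table]], colClasses = "character",
                          check.names = FALSE, fileEncoding = "UTF-8")
    df <- check_columns(tibble::as_tibble(df), table)
    date_cols <- intersect(names(df), c("exposure_date", "condition_date",
                                        "start_date", "end_date"))
    for (dc in date_cols) {
      df[[dc]] <- parse_iso_dates(df[[dc]], basename(files[[table]]), dc)
    }
    df
  }

  raw <- lapply(stats::setNames(nm = names(.cdm_files)), read_one)
  resolve_cdm(raw, registry)
}

#' Construct `cdm_tables` from in-memory raw tables
#'
#' Same resolution and validation path as [load_cdm_tables()], for tables
#' built in code (e.g. by the synthetic generator).
#'
#' @param person,drug_exposure,condition_occurrence,observation_period
#'   Data frames in the raw file schema (dates as `Date`).
#' @inheritParams load_cdm_tables
#' @return A `cdm_tables` object.
#' @export
cdm_tables <- function(person = NULL, drug_exposure = NULL,
                       condition_occurrence = NULL,
                       observation_period = NULL,
                       registry = default_concept_registry()) {
  raw <- empty_raw_tables()
  override <- list(person = person, drug_exposure = drug_exposure,
                   condition_occurrence = condition_occurrence,
                   observation_period = observation_period)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) {
      raw[[nm]] <- check_columns(tibble::as_tibble(override[[nm]]), nm)
    }
  }
  for (nm in names(raw)) {
    for (dc in intersect(names(raw[[nm]]), c("exposure_date", "condition_date",
                                             "start_date", "end_date"))) {
      if (!inherits(raw[[nm]][[dc]], "Date")) {
        raw[[nm]][[dc]] <- parse_iso_dates(raw[[nm]][[dc]], nm, dc)
      }
    }
  }
  resolve_cdm(raw, registry)
}

#' @export
print.cdm_tables <- function(x, ...) {
  cat("<cdm_tables>\n")
  cat(sprintf("  person:               %6d\n", nrow(x$person)))
  cat(sprintf("  drug_exposure:        %6d\n", nrow(x$drug_exposure)))
  cat(sprintf("  condition_occurrence: %6d\n", nrow(x$condition_occurrence)))
  cat(sprintf("  observation_period:   %6d\n", nrow(x$observation_period)))
  if (nrow(x$load_report) > 0) {
    cat("  load report:\n")
    for (i in seq_len(nrow(x$load_report))) {
      cat(sprintf("    %s: %d\n", x$load_report$issue[i], x$load_report$n[i]))
    }
  }
  invisible(x)
}

#' Write `cdm_tables` back to CSV files
#'
#' Serializes the four tables in the raw file schema (dates as ISO-8601
#' strings). Loading the written files with the same registry reproduces the
#' tables field-for-field.
#'
#' @param tables A `cdm_tables` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_cdm_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "cdm_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw <- list(
    person = tables$person,
    drug_exposure = tables$drug_exposure[, .cdm_schemas$drug_exposure],
    condition_occurrence =
      tables$condition_occurrence[, .cdm_schemas$condition_occurrence],
    observation_period = tables$observation_period
  )
  paths <- character(0)
  for (nm in names(raw)) {
    df <- as.data.frame(raw[[nm]])
    for (dc in intersect(names(df), c("exposure_date", "condition_date",
                                      "start_date", "end_date"))) {
      df[[dc]] <- format(df[[dc]], "%Y-%m-%d")
    }
    path <- file.path(dir, .cdm_files[[nm]])
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    paths[nm] <- path
  }
  invisible(paths)
}
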