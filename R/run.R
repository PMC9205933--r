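# End-to-end orchestration ---------------------------------------------------

write_output_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (dc in names(df)) {
    if (inherits(df[[dc]], "Date")) df[[dc]] <- format(df[[dc]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' Orchestrates load -> cohort -> pathway mining (pooled, per era, and per
#' site with aggregate-only merging) -> transition summaries -> intensity
#' tables (all-patients and two-year-sensitivity scopes) -> persistence
#' breakdown, and writes every artifact with deterministic ordering. The
#' merged per-site tree is checked against the pooled tree; a mismatch
#' aborts the run.
#'
#' Outputs in `output_dir`: `load_report.csv`, `cohort.csv`, `attrition.csv`,
#' `pathways.csv` (full-depth pathway counts per stratum), `transitions.csv`,
#' `sunburst.json` and `sankey.json` (depth-`max_depth` trees per stratum),
#' `intensity.csv` (both scopes), `persistence.csv` and `manifest.json`
#' (every file with its data row count).
#'
#' @param input_dir Directory with the four CSV tables (ignored when
#'   `tables` is given). If it contains `concept_registry.json`, that
#'   registry is used unless `registry` is supplied explicitly.
#' @param output_dir Output directory (created if needed).
#' @param tables Optional pre-loaded `cdm_tables`.
#' @param registry Concept registry; default: the registry JSON next to the
#'   input tables if present, else [default_concept_registry()].
#' @param config A [cohort_config()].
#' @param max_depth Truncation depth for the diagram exports (default 3).
#' @return The manifest tibble (`file`, `rows`), invisibly.
#' @export
run_pipeline <- function(input_dir = NULL, output_dir, tables = NULL,
                         registry = NULL, config = cohort_config(),
                         max_depth = 3) {
  if (is.null(tables)) {
    if (is.null(registry)) {
      reg_path <- file.path(input_dir, "concept_registry.json")
      registry <- if (file.exists(reg_path)) read_concept_registry(reg_path)
                  else default_concept_registry()
    }
    tables <- load_cdm_tables(input_dir, registry = registry)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  built <- build_cohort(tables, config)
  cohort <- built$cohort
  exposures <- cohort_exposures(tables, cohort)

  # pathway trees: pooled + per era, at diagram depth and full depth
  mine <- function(stratify_by, depth) {
    if (nrow(cohort) == 0) return(list())
    mine_pathways(cohort, exposures, stratify_by = stratify_by,
                  max_depth = depth)
  }
  trees <- c(mine("none", max_depth), mine("era", max_depth))
  trees_full <- c(mine("none", Inf), mine("era", Inf))

  # aggregate-only site merge must reproduce the pooled tree
  if (nrow(cohort) > 0 && length(unique(cohort$site_id)) > 1) {
    merged <- merge_pathway_trees(mine("site", max_depth))
    pooled <- trees[["all"]]
    if (!identical(dplyr::arrange(merged$nodes, .data$sequence),
                   dplyr::arrange(pooled$nodes, .data$sequence)) ||
        merged$root != pooled$root) {
      stop("pathway_miner: per-site merge does not reproduce the pooled tree",
           call. = FALSE)
    }
  }

  pathways_tbl <- dplyr::bind_rows(lapply(names(trees_full), function(s) {
    tbl <- pathway_table(trees_full[[s]])
    if (nrow(tbl) == 0) return(NULL)
    dplyr::mutate(tbl, stratum = s, .before = 1)
  }))
  if (is.null(pathways_tbl) || nrow(pathways_tbl) == 0) {
    pathways_tbl <- tibble::tibble(stratum = character(),
                                   sequence = character(), depth = integer(),
                                   n = integer())
  }
  pathways_tbl <- dplyr::arrange(pathways_tbl, .data$stratum,
                                 dplyr::desc(.data$n), .data$sequence)

  transitions_tbl <- dplyr::bind_rows(lapply(names(trees_full), function(s) {
    tree <- trees_full[[s]]
    out <- list()
    level <- 1
    while (sum(tree$nodes$count[tree$nodes$depth == level]) > 0) {
      out[[level]] <- dplyr::mutate(transition_summary(tree, level),
                                    stratum = s, .before = 1)
      level <- level + 1
    }
    dplyr::bind_rows(out)
  }))
  if (is.null(transitions_tbl) || nrow(transitions_tbl) == 0) {
    transitions_tbl <- tibble::tibble(stratum = character(),
                                      level = integer(), n_at_risk = integer(),
                                      continued_n = integer(),
                                      switched_n = integer(),
                                      continued_fraction = numeric(),
                                      switched_fraction = numeric())
  }

  intensity_tbl <- dplyr::bind_rows(
    dplyr::mutate(intensity_table(cohort, exposures,
                                  intensity_config("all_patients")),
                  scope = "all_patients", .before = 1),
    dplyr::mutate(intensity_table(cohort, exposures,
                                  intensity_config("min_2y_followup")),
                  scope = "min_2y_followup", .before = 1))
  persistence_tbl <- persistence_breakdown(cohort, exposures)

  manifest <- list()
  add_csv <- function(df, name) {
    rows <- write_output_csv(df, file.path(output_dir, name))
    manifest[[length(manifest) + 1]] <<- list(file = name, rows = rows)
  }
  add_json <- function(x, name, rows) {
    jsonlite::write_json(x, file.path(output_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest[[length(manifest) + 1]] <<- list(file = name,
                                              rows = as.integer(rows))
  }

  add_csv(tables$load_report, "load_report.csv")
  add_csv(cohort, "cohort.csv")
  add_csv(built$attrition, "attrition.csv")
  add_csv(pathways_tbl, "pathways.csv")
  add_csv(transitions_tbl, "transitions.csv")
  add_json(lapply(trees, to_sunburst), "sunburst.json", length(trees))
  add_json(lapply(trees, to_sankey), "sankey.json", length(trees))
  add_csv(intensity_tbl, "intensity.csv")
  add_csv(persistence_tbl, "persistence.csv")

  manifest_tbl <- dplyr::bind_rows(lapply(manifest, tibble::as_tibble))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_tbl)
}
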