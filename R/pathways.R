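# Line-of-therapy derivation and pathway trees ------------------------------

#' Derive a patient's lines of therapy
#'
#' Collapses a date-ordered exposure sequence into lines of therapy: each
#' distinct drug opens a line at its first appearance, and later
#' re-prescriptions of a drug already used in an earlier line do not open a
#' new line. The result is the stable first-appearance deduplication of the
#' exposure sequence.
#'
#' @param ingredients Character vector of drug ingredient names, one per
#'   exposure record.
#' @param dates Optional vector of exposure dates (or integer day offsets).
#'   When given, exposures are ordered by date with same-day ties broken by
#'   the canonical ingredient order; when omitted, `ingredients` is taken as
#'   already ordered.
#' @return Character vector of distinct ingredients in line order.
#' @export
#' @examples
#' derive_lines(c("bevacizumab", "triamcinolone", "bevacizumab",
#'                "dexamethasone"))
derive_lines <- function(ingredients, dates = NULL) {
  if (length(ingredients) == 0) {
    stop("contract violation: empty exposure list (every cohort member has ",
         "at least the index exposure)", call. = FALSE)
  }
  rk <- ingredient_rank(ingredients)
  if (anyNA(rk)) {
    stop("unknown drug ingredient(s): ",
         paste(unique(ingredients[is.na(rk)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(dates)) {
    ingredients <- ingredients[order(dates, rk)]
  }
  ingredients[!duplicated(ingredients)]
}

# Pathway tree ---------------------------------------------------------------

new_pathway_tree <- function(root, nodes, max_depth) {
  nodes <- dplyr::arrange(nodes, .data$depth, .data$sequence)
  structure(list(root = as.integer(root),
                 nodes = nodes,
                 max_depth = max_depth),
            class = "pathway_tree")
}

seq_string <- function(lines) paste(short_name_of(lines), collapse = ">")

#' Build a pathway tree from line sequences
#'
#' Counts every prefix of each (depth-truncated) line sequence. Sequences
#' longer than `max_depth` are folded into their depth-`max_depth` prefix
#' node. Node keys are short-name strings such as `"bev>triam"`.
#'
#' @param line_list List of character vectors of ingredient names (one
#'   sequence per patient).
#' @param max_depth Truncation depth (default 3; `Inf` keeps full sequences,
#'   which can be at most 5 lines long).
#' @return A `pathway_tree`: list with `root` (number of sequences), `nodes`
#'   (tibble `sequence`, `depth`, `count`) and `max_depth`.
#' @export
pathway_tree <- function(line_list, max_depth = 3) {
  prefixes <- unname(unlist(lapply(line_list, function(lines) {
    lines <- lines[seq_len(min(length(lines), max_depth))]
    vapply(seq_along(lines),
           function(d) seq_string(lines[seq_len(d)]), character(1))
  })))
  nodes <- if (length(prefixes) == 0) {
    tibble::tibble(sequence = character(), depth = integer(),
                   count = integer())
  } else {
    tibble::tibble(sequence = prefixes) |>
      dplyr::count(.data$sequence, name = "count") |>
      dplyr::mutate(depth = lengths(strsplit(.data$sequence, ">",
                                             fixed = TRUE))) |>
      dplyr::select("sequence", "depth", "count")
  }
  new_pathway_tree(length(line_list), nodes, max_depth)
}

#' @export
print.pathway_tree <- function(x, ...) {
  cat(sprintf("<pathway_tree> %d pathway(s), %d node(s), max depth %s\n",
              x$root, nrow(x$nodes), format(x$max_depth)))
  if (nrow(x$nodes) > 0) print(x$nodes, n = 15)
  invisible(x)
}

# count of one-step extensions for each node (0 for nodes with no children)
node_extension_counts <- function(tree) {
  nodes <- tree$nodes
  if (nrow(nodes) == 0) return(integer(0))
  parent <- sub(">[^>]*$", "", nodes$sequence)
  parent[nodes$depth == 1] <- NA_character_
  ext <- tapply(nodes$count, factor(parent, levels = nodes$sequence), sum)
  ext <- as.integer(ext)
  ext[is.na(ext)] <- 0L
  ext
}

# patients whose (truncated) pathway stops exactly at each node
node_stop_counts <- function(tree) {
  tree$nodes$count - node_extension_counts(tree)
}

#' Complete pathways and their counts
#'
#' @param tree A `pathway_tree`.
#' @return Tibble `sequence`, `depth`, `n`: the distinct (depth-truncated)
#'   pathways with the number of patients following exactly each one.
#' @export
pathway_table <- function(tree) {
  stopifnot(inherits(tree, "pathway_tree"))
  stops <- node_stop_counts(tree)
  out <- tree$nodes[stops > 0, c("sequence", "depth")]
  out$n <- stops[stops > 0]
  dplyr::arrange(out, dplyr::desc(.data$n), .data$sequence)
}

#' Mine pathway trees from a cohort
#'
#' Derives each member's line sequence from their post-index exposures and
#' aggregates the sequences into one pathway tree per stratum.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param tables The `cdm_tables` the cohort was built from (or a
#'   pre-computed [cohort_exposures()] tibble).
#' @param stratify_by `"none"` (single tree named `"all"`), `"era"` or
#'   `"site"`.
#' @param max_depth Tree truncation depth (default 3).
#' @param window_days Pathway observation window: only exposures with
#'   `day < window_days` contribute (default `Inf`, i.e. index to observation
#'   end).
#' @return Named list of `pathway_tree` objects, one per stratum.
#' @export
mine_pathways <- function(cohort, tables, stratify_by = c("none", "era", "site"),
                          max_depth = 3, window_days = Inf) {
  stratify_by <- match.arg(stratify_by)
  exposures <- if (inherits(tables, "cdm_tables")) {
    cohort_exposures(tables, cohort)
  } else {
    tables
  }
  exposures <- dplyr::filter(exposures, .data$day < window_days)

  lines_by_person <- lapply(
    split(exposures$ingredient,
          factor(exposures$person_id, levels = cohort$person_id)),
    function(ing) if (length(ing) == 0) character(0) else derive_lines(ing)
  )
  empty <- vapply(lines_by_person, length, integer(1)) == 0
  if (any(empty)) {
    stop("cohort member(s) with no exposures in the pathway window: ",
         paste(utils::head(names(lines_by_person)[empty], 5), collapse = ", "),
         call. = FALSE)
  }

  strata <- switch(stratify_by,
                   none = rep("all", nrow(cohort)),
                   era = cohort$era,
                   site = cohort$site_id)
  labels <- sort(unique(strata))
  out <- lapply(labels, function(s) {
    pathway_tree(lines_by_person[strata == s], max_depth = max_depth)
  })
  names(out) <- labels
  out
}

#' Continuation and switching at a treatment-line level
#'
#' At level L, patients at risk are those with at least L lines; those with
#' exactly L lines "continued" their level-L drug, while those with a line
#' L+1 "switched". At the tree's truncation depth, deeper switches are not
#' visible and the continued fraction is 1 by construction; use a full-depth
#' tree for levels near the truncation depth.
#'
#' @param tree A `pathway_tree`.
#' @param level Line level (1 = first line to second line, etc.).
#' @return One-row tibble: `level`, `n_at_risk`, `continued_n`, `switched_n`,
#'   `continued_fraction`, `switched_fraction`.
#' @export
transition_summary <- function(tree, level) {
  stopifnot(inherits(tree, "pathway_tree"), level >= 1)
  n_at_risk <- sum(tree$nodes$count[tree$nodes$depth == level])
  if (n_at_risk == 0) {
    stop("zero denominator: no pathway has ", level, " or more lines",
         call. = FALSE)
  }
  switched <- sum(tree$nodes$count[tree$nodes$depth == level + 1])
  tibble::tibble(level = as.integer(level),
                 n_at_risk = as.integer(n_at_risk),
                 continued_n = as.integer(n_at_risk - switched),
                 switched_n = as.integer(switched),
                 continued_fraction = (n_at_risk - switched) / n_at_risk,
                 switched_fraction = switched / n_at_risk)
}

#' Second-line drug breakdown within a first-line stratum
#'
#' Among patients whose first-line drug is in `first_line`, the fraction
#' whose second line is each drug (denominator: all such patients, so the
#' fractions plus the `"none"` row sum to 1).
#'
#' @param tree A `pathway_tree`.
#' @param first_line Ingredient name(s), or a class (`"anti_VEGF"` /
#'   `"steroid"`).
#' @return Tibble `second_drug` (ingredient or `"none"`), `n`, `fraction`.
#' @export
switch_breakdown <- function(tree, first_line) {
  stopifnot(inherits(tree, "pathway_tree"))
  if (length(first_line) == 1 && first_line %in% c("anti_VEGF", "steroid")) {
    first_line <- drug_ingredients()$ingredient[
      drug_ingredients()$drug_class == first_line]
  }
  shorts <- short_name_of(first_line)
  d1 <- tree$nodes[tree$nodes$depth == 1 & tree$nodes$sequence %in% shorts, ]
  denom <- sum(d1$count)
  if (denom == 0) {
    stop("zero denominator: no pathway starts with ",
         paste(first_line, collapse = "/"), call. = FALSE)
  }
  d2 <- tree$nodes[tree$nodes$depth == 2, ]
  parts <- strsplit(d2$sequence, ">", fixed = TRUE)
  keep <- vapply(parts, function(p) p[1] %in% shorts, logical(1))
  d2 <- d2[keep, ]
  second <- vapply(parts[keep], `[`, character(1), 2)
  out <- tibble::tibble(second_drug = ingredient_from_short(second),
                        n = d2$count) |>
    dplyr::group_by(.data$second_drug) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  out <- dplyr::bind_rows(
    out, tibble::tibble(second_drug = "none", n = as.integer(denom - sum(out$n)))
  )
  out$fraction <- out$n / denom
  dplyr::arrange(out, .data$second_drug == "none", dplyr::desc(.data$n),
                 .data$second_drug)
}

#' Merge per-site pathway trees into a pooled tree
#'
#' Node-wise sum of counts; the aggregate-only analogue of pooling
#' patient-level data. Merging is associative and commutative, and merging
#' per-site trees equals mining the pooled cohort.
#'
#' @param ... `pathway_tree` objects (or a single list of them). All must
#'   share `max_depth`.
#' @return A `pathway_tree`.
#' @export
merge_pathway_trees <- function(...) {
  trees <- list(...)
  if (length(trees) == 1 && !inherits(trees[[1]], "pathway_tree")) {
    trees <- trees[[1]]
  }
  stopifnot(length(trees) >= 1,
            all(vapply(trees, inherits, logical(1), what = "pathway_tree")))
  depths <- vapply(trees, function(t) as.numeric(t$max_depth), numeric(1))
  if (length(unique(depths)) > 1) {
    stop("cannot merge pathway trees with different max_depth", call. = FALSE)
  }
  nodes <- dplyr::bind_rows(lapply(trees, function(t) t$nodes)) |>
    dplyr::group_by(.data$sequence, .data$depth) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  new_pathway_tree(sum(vapply(trees, function(t) t$root, integer(1))),
                   nodes, trees[[1]]$max_depth)
}

# Diagram exports ------------------------------------------------------------

#' Sunburst data export
#'
#' Nested name/value/children structure. Each node's children are its
#' one-step extensions plus an explicit `"stop"` leaf carrying the patients
#' who had no further line, so every ring conserves its parent's total.
#'
#' @param tree A `pathway_tree`.
#' @return A nested list (serialize with `jsonlite::toJSON(auto_unbox = TRUE)`).
#' @export
to_sunburst <- function(tree) {
  stopifnot(inherits(tree, "pathway_tree"))
  nodes <- tree$nodes
  stops <- node_stop_counts(tree)
  build <- function(prefix, depth, value) {
    if (depth >= 1) {
      child_idx <- which(nodes$depth == depth + 1 &
                           startsWith(nodes$sequence, paste0(prefix, ">")))
    } else {
      child_idx <- which(nodes$depth == 1)
    }
    children <- lapply(child_idx, function(i) {
      parts <- strsplit(nodes$sequence[i], ">", fixed = TRUE)[[1]]
      build(nodes$sequence[i], nodes$depth[i], nodes$count[i])
    })
    stop_n <- if (depth >= 1) {
      stops[match(prefix, nodes$sequence)]
    } else {
      tree$root - sum(nodes$count[nodes$depth == 1])
    }
    if (stop_n > 0 || (length(children) == 0 && depth >= 1)) {
      children <- c(children, list(list(name = "stop",
                                        value = as.integer(stop_n))))
    }
    name <- if (depth == 0) "root" else {
      parts <- strsplit(prefix, ">", fixed = TRUE)[[1]]
      parts[length(parts)]
    }
    out <- list(name = name, value = as.integer(value))
    if (length(children) > 0) out$children <- children
    out
  }
  build("", 0L, tree$root)
}

#' Sankey data export
#'
#' Nodes are labeled `"<line index>:<drug>"`; a per-level terminal
#' `"<level>:stop"` node absorbs patients with no further line, so every
#' node's outflow equals its inflow.
#'
#' @param tree A `pathway_tree`.
#' @return List with `nodes` (tibble `id`, `name`) and `links` (tibble
#'   `source`, `target` as 0-based node ids, `source_name`, `target_name`,
#'   `value`).
#' @export
to_sankey <- function(tree) {
  stopifnot(inherits(tree, "pathway_tree"))
  nodes <- tree$nodes
  if (nrow(nodes) == 0) {
    return(list(nodes = tibble::tibble(id = integer(), name = character()),
                links = tibble::tibble(source = integer(), target = integer(),
                                       source_name = character(),
                                       target_name = character(),
                                       value = integer())))
  }
  parts <- strsplit(nodes$sequence, ">", fixed = TRUE)
  label_of <- function(i) paste0(nodes$depth[i], ":", parts[[i]][nodes$depth[i]])
  labels <- vapply(seq_len(nrow(nodes)), label_of, character(1))
  stops <- node_stop_counts(tree)

  links <- list()
  # drug -> drug transitions
  deeper <- which(nodes$depth > 1)
  if (length(deeper) > 0) {
    parent_seq <- vapply(deeper, function(i) {
      paste(parts[[i]][seq_len(nodes$depth[i] - 1)], collapse = ">")
    }, character(1))
    links[[1]] <- tibble::tibble(
      source_name = labels[match(parent_seq, nodes$sequence)],
      target_name = labels[deeper],
      value = nodes$count[deeper])
  }
  # drug -> stop
  with_stop <- which(stops > 0)
  if (length(with_stop) > 0) {
    links[[length(links) + 1]] <- tibble::tibble(
      source_name = labels[with_stop],
      target_name = paste0(nodes$depth[with_stop] + 1L, ":stop"),
      value = stops[with_stop])
  }
  links <- dplyr::bind_rows(links) |>
    dplyr::group_by(.data$source_name, .data$target_name) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")

  node_names <- unique(c(labels[order(nodes$depth, nodes$sequence)],
                         sort(unique(links$target_name))))
  node_tbl <- tibble::tibble(id = seq_along(node_names) - 1L,
                             name = node_names)
  links <- links |>
    dplyr::mutate(source = node_tbl$id[match(.data$source_name, node_tbl$name)],
                  target = node_tbl$id[match(.data$target_name, node_tbl$name)]) |>
    dplyr::select("source", "target", "source_name", "target_name", "value") |>
    dplyr::arrange(.data$source, .data$target)
  list(nodes = node_tbl, links = links)
}
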