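# Drug ingredient reference ------------------------------------------------

# Fixed ingredient order; also the tie-break order for same-day exposures.
.ingredients <- c("bevacizumab", "ranibizumab", "aflibercept",
                  "triamcinolone", "dexamethasone")
.ingredient_class <- c(bevacizumab = "anti_VEGF", ranibizumab = "anti_VEGF",
                       aflibercept = "anti_VEGF", triamcinolone = "steroid",
                       dexamethasone = "steroid")
.ingredient_short <- c(bevacizumab = "bev", ranibizumab = "ran",
                       aflibercept = "afl", triamcinolone = "triam",
                       dexamethasone = "dex")

#' Intravitreal drug ingredients and their classes
#'
#' The five target drugs for macular edema secondary to retinal vein
#' occlusion: three anti-VEGF agents (bevacizumab, ranibizumab, aflibercept)
#' and two steroids (triamcinolone, dexamethasone). The row order is the
#' canonical ingredient order used to break ties between same-day exposures.
#'
#' @return A tibble with columns `ingredient`, `drug_class`
#'   (`"anti_VEGF"` or `"steroid"`) and `short_name` (the abbreviation used
#'   in pathway sequence strings, e.g. `"bev"`).
#' @export
#' @examples
#' drug_ingredients()
drug_ingredients <- function() {
  tibble::tibble(
    ingredient = .ingredients,
    drug_class = unname(.ingredient_class[.ingredients]),
    short_name = unname(.ingredient_short[.ingredients])
  )
}

#' Drug class of an ingredient
#'
#' @param ingredient Character vector of ingredient names.
#' @return Character vector, `"anti_VEGF"` or `"steroid"`.
#' @export
drug_class_of <- function(ingredient) {
  bad <- setdiff(unique(ingredient), .ingredients)
  if (length(bad) > 0) {
    stop("unknown drug ingredient(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(.ingredient_class[ingredient])
}

# rank in the canonical order (1 = bevacizumab ... 5 = dexamethasone)
ingredient_rank <- function(ingredient) {
  match(ingredient, .ingredients)
}

short_name_of <- function(ingredient) {
  unname(.ingredient_short[ingredient])
}

ingredient_from_short <- function(short) {
  full <- names(.ingredient_short)[match(short, .ingredient_short)]
  if (anyNA(full)) {
    stop("unknown short drug name(s): ",
         paste(short[is.na(full)], collapse = ", "), call. = FALSE)
  }
  full
}

# Concept sets ---------------------------------------------------------------

#' Create a concept set
#'
#' A concept set is a named, enumerated list of (vocabulary, code) pairs that
#' defines either one drug ingredient or a diagnosis group. Resolution at load
#' time is by exact (vocabulary, code) match; no vocabulary hierarchy is
#' traversed.
#'
#' @param set_id Short identifier, unique within a registry. Drug sets must
#'   use the ingredient name as `set_id`; diagnosis sets use e.g. `"rvo"` or
#'   `"exclusion"`.
#' @param name Human-readable label.
#' @param kind `"drug"` or `"diagnosis"`.
#' @param codes A data frame with columns `vocabulary` and `code`.
#' @return An object of class `concept_set`.
#' @export
concept_set <- function(set_id, name, kind = c("drug", "diagnosis"), codes) {
  kind <- match.arg(kind)
  stopifnot(is.character(set_id), length(set_id) == 1, nzchar(set_id))
  codes <- tibble::as_tibble(codes)
  if (!all(c("vocabulary", "code") %in% names(codes))) {
    stop("codes must have columns 'vocabulary' and 'code'", call. = FALSE)
  }
  codes <- codes[, c("vocabulary", "code")]
  codes$vocabulary <- as.character(codes$vocabulary)
  codes$code <- as.character(codes$code)
  if (nrow(codes) == 0) {
    stop("concept set '", set_id, "' has no codes", call. = FALSE)
  }
  if (anyDuplicated(codes)) {
    stop("concept set '", set_id, "' has duplicate (vocabulary, code) pairs",
         call. = FALSE)
  }
  if (kind == "drug" && !set_id %in% .ingredients) {
    stop("drug concept set_id must be one of: ",
         paste(.ingredients, collapse = ", "), call. = FALSE)
  }
  structure(list(set_id = set_id, name = name, kind = kind, codes = codes),
            class = "concept_set")
}

#' @export
print.concept_set <- function(x, ...) {
  cat(sprintf("<concept_set> %s (%s): %s; %d code(s)\n",
              x$set_id, x$kind, x$name, nrow(x$codes)))
  invisible(x)
}

#' Build a concept registry
#'
#' @param ... `concept_set` objects. `set_id`s must be unique; exactly the
#'   diagnosis sets `"rvo"` and `"exclusion"` are required for cohort
#'   building, along with one drug set per target ingredient.
#' @return A named list of `concept_set`s with class `concept_registry`.
#' @export
concept_registry <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "concept_set")) {
    sets <- sets[[1]]
  }
  ok <- vapply(sets, inherits, logical(1), what = "concept_set")
  if (!all(ok)) stop("all registry entries must be concept_set objects",
                     call. = FALSE)
  ids <- vapply(sets, function(s) s$set_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate set_id in registry: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- ids
  structure(sets, class = "concept_registry")
}

#' Default concept registry with placeholder codes
#'
#' Ships synthetic placeholder codes (the real SNOMED-CT code lists live in
#' hospital vocabularies and are not redistributed): one drug set per target
#' ingredient, an `rvo` diagnosis set, and an `exclusion` set covering
#' exudative AMD, choroidal neovascularization of other cause, central serous
#' chorioretinopathy, uveitis and inherited retinal disease.
#'
#' @return A `concept_registry`.
#' @export
default_concept_registry <- function() {
  drug_set <- function(ing, codes) {
    concept_set(ing, paste("intravitreal", ing), "drug",
                tibble::tibble(vocabulary = "demo-rx", code = codes))
  }
  concept_registry(
    drug_set("bevacizumab",   c("BEV01", "BEV02")),
    drug_set("ranibizumab",   c("RAN01")),
    drug_set("aflibercept",   c("AFL01")),
    drug_set("triamcinolone", c("TRI01", "TRI02")),
    drug_set("dexamethasone", c("DEX01")),
    concept_set("rvo", "retinal vein occlusion (incl. central/branch)",
                "diagnosis",
                tibble::tibble(vocabulary = "demo-dx",
                               code = c("RVO01", "RVO02", "RVO03"))),
    concept_set("exclusion", "other retinal disorders (exclusion)",
                "diagnosis",
                tibble::tibble(vocabulary = "demo-dx",
                               code = c("AMD01", "CNV01", "CSC01",
                                        "UVE01", "IRD01")))
  )
}

registry_lookup <- function(registry, kind) {
  sets <- Filter(function(s) s$kind == kind, registry)
  if (length(sets) == 0) {
    return(tibble::tibble(vocabulary = character(), code = character(),
                          set_id = character()))
  }
  dplyr::bind_rows(lapply(sets, function(s) {
    dplyr::mutate(s$codes, set_id = s$set_id)
  }))
}

#' Read / write a concept registry as JSON
#'
#' @param path File path.
#' @return `read_concept_registry()` returns a `concept_registry`;
#'   `write_concept_registry()` returns `path` invisibly.
#' @export
read_concept_registry <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  sets <- lapply(raw$concept_sets, function(s) {
    codes <- dplyr::bind_rows(lapply(s$codes, tibble::as_tibble))
    concept_set(s$set_id, s$name, s$kind, codes)
  })
  concept_registry(sets)
}

#' @rdname read_concept_registry
#' @param registry A `concept_registry`.
#' @export
write_concept_registry <- function(registry, path) {
  stopifnot(inherits(registry, "concept_registry"))
  out <- list(concept_sets = lapply(unname(registry), function(s) {
    list(set_id = s$set_id, name = s$name, kind = s$kind, codes = s$codes)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
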