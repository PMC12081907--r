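#' Opioid lexicon handling
#'
#' The mention detector works from a *class-annotated lexicon*: a table of
#' surface terms (canonical drug names, brand names, common misspellings,
#' multi-word street names), each mapped to a canonical drug and to two
#' class labels — a mu-opioid receptor activity class and a synthesis class.
#' Surface terms must be unambiguous: a term that could denote two different
#' drugs is rejected rather than guessed at.
#'
#' @name lexicon
NULL

RECEPTOR_CLASSES <- c("heroin", "full_agonist", "partial_agonist",
                      "mixed_agonist", "antagonist")
SYNTHESIS_CLASSES <- c("heroin", "synthetic", "natural_semisynthetic",
                       "other_opioid", "excluded")

#' Load and validate a drug-term lexicon
#'
#' Reads a CSV with columns `surface_term`, `canonical_drug`,
#' `receptor_class`, `synthesis_class`. Terms are lowercased; duplicate
#' surface terms, terms mapping to more than one drug, unknown class labels,
#' and inconsistent class labels within one canonical drug are all errors.
#'
#' @param path path to a lexicon CSV file.
#' @return a `data.frame` of class `opioid_lexicon` with the four columns
#'   above, one row per surface term.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  lx <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("surface_term", "canonical_drug", "receptor_class",
                "synthesis_class")
  missing <- setdiff(required, names(lx))
  if (length(missing)) {
    stop("lexicon is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lx <- lx[required]
  validate_lexicon(lx)
}

#' @rdname load_lexicon
#' @param lx a data.frame with the four lexicon columns (e.g. built in code).
#' @export
validate_lexicon <- function(lx) {
  lx$surface_term <- trimws(tolower(lx$surface_term))
  lx$canonical_drug <- trimws(tolower(lx$canonical_drug))
  if (nrow(lx) == 0L) stop("lexicon is empty", call. = FALSE)
  if (any(lx$surface_term == "")) stop("lexicon has empty surface terms",
                                       call. = FALSE)

  bad_rc <- !(lx$receptor_class %in% RECEPTOR_CLASSES)
  bad_sc <- !(lx$synthesis_class %in% SYNTHESIS_CLASSES)
  if (any(bad_rc) || any(bad_sc)) {
    rows <- which(bad_rc | bad_sc)
    stop("unknown class label(s) in lexicon row(s): ",
         paste(sprintf("%d (%s/%s)", rows, lx$receptor_class[rows],
                       lx$synthesis_class[rows]), collapse = "; "),
         call. = FALSE)
  }

  dup <- duplicated(lx$surface_term)
  if (any(dup)) {
    terms <- unique(lx$surface_term[dup])
    maps <- vapply(terms, function(tm) {
      length(unique(lx$canonical_drug[lx$surface_term == tm]))
    }, integer(1))
    if (any(maps > 1L)) {
      stop("ambiguous surface term(s) mapping to multiple drugs: ",
           paste(terms[maps > 1L], collapse = ", "), call. = FALSE)
    }
    stop("duplicate surface term(s): ", paste(terms, collapse = ", "),
         call. = FALSE)
  }

  # one (receptor, synthesis) pair per canonical drug
  cls <- unique(lx[c("canonical_drug", "receptor_class", "synthesis_class")])
  ndrug <- table(cls$canonical_drug)
  if (any(ndrug > 1L)) {
    stop("inconsistent class labels for drug(s): ",
         paste(names(ndrug)[ndrug > 1L], collapse = ", "), call. = FALSE)
  }
  class(lx) <- c("opioid_lexicon", "data.frame")
  rownames(lx) <- NULL
  lx
}

#' Default shipped lexicon
#'
#' A fixture lexicon covering the tracked opioids under their canonical
#' spellings plus a small set of illustrative brand names, street names and
#' misspelling variants. It is a curated fixture, not a reconstruction of an
#' embedding-derived term list.
#'
#' @return an `opioid_lexicon` data.frame.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "opioid_lexicon.csv",
                           package = "opiwatch", mustWork = TRUE))
}

#' Resolve a reporting category to a set of canonical drugs
#'
#' Categories mirror the benchmark reporting conventions: the synthesis-based
#' mortality categories (`"synthetic"`, `"natural_semisynthetic"`,
#' `"heroin"`), the receptor-activity classes, the umbrella
#' `"all_opioids"` category, or any single canonical drug. Methadone, which
#' the mortality classification excludes from the synthesis classes, resolves
#' only under `"all_opioids"`, receptor-class queries, and its own name.
#'
#' @param category a category label (see Details) or canonical drug name.
#' @param lexicon an `opioid_lexicon`.
#' @return character vector of canonical drug names.
#' @export
resolve_category <- function(category, lexicon) {
  stopifnot(inherits(lexicon, "opioid_lexicon"), length(category) == 1L)
  category <- tolower(trimws(category))
  drugs <- unique(lexicon$canonical_drug)
  cls <- unique(lexicon[c("canonical_drug", "receptor_class",
                          "synthesis_class")])

  if (category == "all_opioids") return(sort(drugs))
  if (category %in% c("synthetic", "natural_semisynthetic", "heroin")) {
    return(sort(cls$canonical_drug[cls$synthesis_class == category]))
  }
  if (category %in% c("full_agonist", "partial_agonist", "mixed_agonist",
                      "antagonist")) {
    return(sort(cls$canonical_drug[cls$receptor_class == category]))
  }
  if (category %in% drugs) return(category)
  stop("unknown category '", category, "'; valid categories: all_opioids, ",
       "synthetic, natural_semisynthetic, heroin, full_agonist, ",
       "partial_agonist, mixed_agonist, antagonist, or a canonical drug (",
       paste(sort(drugs), collapse = ", "), ")", call. = FALSE)
}

#' Default location-community map
#'
#' Maps location community names to their city, state, and U.S. census
#' region (Northeast, Midwest, South, West).
#'
#' @return a validated location map data.frame.
#' @export
default_location_map <- function() {
  load_location_map(system.file("extdata", "location_map.csv",
                                package = "opiwatch", mustWork = TRUE))
}

CENSUS_REGIONS <- c("Northeast", "Midwest", "South", "West")

#' @rdname default_location_map
#' @param path path to a CSV with columns `community`, `state`, `region`
#'   (and optionally `city`).
#' @export
load_location_map <- function(path) {
  if (!file.exists(path)) stop("location map not found: ", path, call. = FALSE)
  lm_ <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("community", "state", "region")
  missing <- setdiff(required, names(lm_))
  if (length(missing)) {
    stop("location map is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lm_$community <- tolower(trimws(lm_$community))
  if (anyDuplicated(lm_$community)) {
    stop("duplicate community names in location map", call. = FALSE)
  }
  bad <- !(lm_$region %in% CENSUS_REGIONS)
  if (any(bad)) {
    stop("unknown region(s): ", paste(unique(lm_$region[bad]), collapse = ", "),
         "; regions must be one of ", paste(CENSUS_REGIONS, collapse = ", "),
         call. = FALSE)
  }
  s2r <- unique(lm_[c("state", "region")])
  multi <- table(s2r$state)
  if (any(multi > 1L)) {
    stop("state(s) mapped to more than one region: ",
         paste(names(multi)[multi > 1L], collapse = ", "), call. = FALSE)
  }
  class(lm_) <- c("location_map", "data.frame")
  lm_
}

#' Default 2020 state population table
#'
#' Census 2020 resident population estimates for the states referenced by
#' the default location map, used for cohort-population concordance checks.
#'
#' @return named numeric vector (state -> population).
#' @export
default_state_populations <- function() {
  df <- read.csv(system.file("extdata", "state_populations_2020.csv",
                             package = "opiwatch", mustWork = TRUE),
                 stringsAsFactors = FALSE)
  setNames(df$population, df$state)
}
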