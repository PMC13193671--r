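#' @title Descriptive completeness and diversity profiling
#' @description Component 3 of the audit: distributions of persons and
#' records across demographic groups, mapped vocabularies, visit types and
#' top clinical concepts. There is no gold-standard distribution; profiles
#' are interpreted against the intended research use. Person-level profiles
#' never double-count a person within one category, and visit-type profiles
#' are multi-membership (a person can have several visit types, so percents
#' may sum above 100).
#' @name profiling
NULL

#' Build a concept dictionary
#'
#' @param df data.frame with columns `concept_id`, `concept_name`,
#'   `vocabulary_id`, `domain_id`. The reserved id `0` ("No matching
#'   concept") is always present; it is added if absent.
#' @return A `concept_dictionary`.
#' @export
concept_dictionary <- function(df) {
  dt <- data.table::as.data.table(df)
  need <- c("concept_id", "concept_name", "vocabulary_id", "domain_id")
  data.table::setnames(dt, tolower(names(dt)))
  if (!all(need %in% names(dt)))
    validation_error(sprintf("dictionary must have columns: %s", paste(need, collapse = ", ")))
  dt <- dt[, need, with = FALSE]
  dt[, concept_id := as.character(concept_id)]
  if (!"0" %in% dt$concept_id) {
    dt <- rbind(data.table::data.table(concept_id = "0",
                                       concept_name = "No matching concept",
                                       vocabulary_id = "None", domain_id = "Metadata"),
                dt)
  } else {
    dt[concept_id == "0", concept_name := "No matching concept"]
  }
  data.table::setkey(dt, concept_id)
  structure(list(entries = dt), class = "concept_dictionary")
}

#' Load a concept dictionary from a delimited file
#'
#' @param path CSV/TSV file with columns `concept_id`, `concept_name`,
#'   `vocabulary_id`, `domain_id`.
#' @return A `concept_dictionary`.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) data_error(sprintf("dictionary file not found: %s", path))
  concept_dictionary(data.table::fread(path, colClasses = "character", na.strings = ""))
}

#' The bundled synthetic concept dictionary
#'
#' A small, fully synthetic dictionary covering the gender/race/ethnicity,
#' visit, condition, drug, measurement, observation and procedure concepts
#' used by the synthetic generator. Not real vocabulary content.
#' @return A `concept_dictionary`.
#' @export
default_dictionary <- function() {
  load_dictionary(system.file("extdata", "synthetic-concepts.csv",
                              package = "cdmaudit", mustWork = TRUE))
}

#' @export
print.concept_dictionary <- function(x, ...) {
  cat(sprintf("<concept_dictionary> %d concepts, %d vocabularies\n",
              nrow(x$entries), data.table::uniqueN(x$entries$vocabulary_id)))
  invisible(x)
}

# label lookup; id 0 -> "No matching concept", unknown ids -> "concept:<id>"
lookup_concept_name <- function(dictionary, ids) {
  ids <- as.character(ids)
  ids[is.na(ids) | trimws(ids) == ""] <- "0"
  nm <- dictionary$entries[data.table::data.table(concept_id = trimws(ids)),
                           on = "concept_id", concept_name]
  miss <- is.na(nm)
  nm[miss] <- paste0("concept:", trimws(ids[miss]))
  nm
}

lookup_vocabulary <- function(dictionary, ids) {
  ids <- as.character(ids)
  unmapped <- is.na(ids) | trimws(ids) == "" | trimws(ids) == "0"
  v <- dictionary$entries[data.table::data.table(concept_id = trimws(ids)),
                          on = "concept_id", vocabulary_id]
  v[unmapped | is.na(v)] <- "Unmapped/Unknown"
  v
}

new_distribution <- function(dimension, unit, entries, denominator,
                             multi_membership = FALSE) {
  entries[, percent := vapply(count, pct1, 0, den = denominator)]
  structure(list(dimension = dimension, unit = unit, entries = entries[],
                 denominator = denominator, multi_membership = multi_membership),
            class = "category_distribution")
}

#' @export
print.category_distribution <- function(x, ...) {
  cat(sprintf("<category_distribution> %s (unit=%s, n=%s%s)\n", x$dimension, x$unit,
              format(x$denominator, big.mark = ","),
              if (x$multi_membership) ", multi-membership" else ""))
  print(x$entries)
  invisible(x)
}

#' Demographic distributions of the person table
#'
#' One distribution each for sex, race and ethnicity, counted in persons
#' over the person-table denominator, with concept labels resolved through
#' the dictionary (id 0 renders as "No matching concept"). Entries are
#' ordered by descending count.
#'
#' @param handle A `dataset_handle`.
#' @param dictionary A [concept_dictionary()].
#' @return Named list of `category_distribution`s (`sex`, `race`,
#'   `ethnicity`), or `NULL` with a warning when the person table is
#'   unavailable.
#' @export
demographic_profile <- function(handle, dictionary = default_dictionary()) {
  if (!table_exists(handle, "person") || row_count(handle, "person") == 0L) {
    warning("person table unavailable or empty; demographic profile not applicable",
            call. = FALSE)
    return(NULL)
  }
  person <- read_table_raw(handle, "person")
  denom <- data.table::uniqueN(person$person_id %||% seq_len(nrow(person)))
  dims <- c(sex = "gender_concept_id", race = "race_concept_id",
            ethnicity = "ethnicity_concept_id")
  out <- lapply(names(dims), function(dim) {
    col <- dims[[dim]]
    if (!col %in% names(person)) {
      warning(sprintf("column-absent: person.%s", col), call. = FALSE)
      ids <- rep(NA_character_, nrow(person))
    } else ids <- person[[col]]
    dd <- data.table::data.table(pid = person$person_id,
                                 category = lookup_concept_name(dictionary, ids))
    ent <- dd[, list(count = data.table::uniqueN(pid)), by = category]
    data.table::setorder(ent, -count, category)
    new_distribution(dim, "persons", ent, denom)
  })
  names(out) <- names(dims)
  out
}

#' Distribution of mapped vocabularies in one table
#'
#' Row-level counts of the vocabulary each record's concept id maps to.
#' Unresolvable or unmapped concept ids are counted under
#' `"Unmapped/Unknown"`, never dropped. Vocabularies below
#' `other_threshold_pct` percent of rows are collapsed into `"Other"`
#' (appended last); larger entries are ordered by descending count.
#'
#' @param handle A `dataset_handle`.
#' @param table,concept_column Target table and concept-id column.
#' @param dictionary A [concept_dictionary()].
#' @param other_threshold_pct Collapse threshold in percent (default 0.5).
#' @return A `category_distribution` with `unit = "rows"`.
#' @export
vocabulary_distribution <- function(handle, table, concept_column,
                                    dictionary = default_dictionary(),
                                    other_threshold_pct = 0.5) {
  table <- tolower(table); concept_column <- tolower(concept_column)
  if (!table_exists(handle, table) || row_count(handle, table) == 0L) {
    warning(sprintf("table '%s' unavailable or empty; vocabulary profile not applicable", table),
            call. = FALSE)
    return(NULL)
  }
  dt <- read_table_raw(handle, table)
  if (!concept_column %in% names(dt))
    validation_error(sprintf("column '%s' absent from '%s'", concept_column, table))
  vocab <- lookup_vocabulary(dictionary, dt[[concept_column]])
  ent <- data.table::data.table(category = vocab)[, list(count = .N), by = category]
  denom <- nrow(dt)
  small <- ent$count / denom * 100 < other_threshold_pct & ent$category != "Unmapped/Unknown"
  if (any(small)) {
    other <- sum(ent$count[small])
    ent <- ent[!small]
    keep_other <- data.table::data.table(category = "Other", count = other)
  } else keep_other <- NULL
  data.table::setorder(ent, -count, category)
  if (!is.null(keep_other)) ent <- rbind(ent, keep_other)
  new_distribution(paste0("vocabulary:", table, ".", concept_column), "rows", ent, denom)
}

#' Visit-type distribution over persons
#'
#' For each visit-type concept, the number of distinct persons with at
#' least one visit of that type, as a percent of all persons. A person
#' with several visit types counts once under each (multi-membership), so
#' percents may sum above 100.
#'
#' @param handle A `dataset_handle`.
#' @param dictionary A [concept_dictionary()].
#' @param visit_table,concept_column,person_column Table layout overrides.
#' @return A `category_distribution` with `unit = "persons"` and
#'   `multi_membership = TRUE`.
#' @export
visit_type_profile <- function(handle, dictionary = default_dictionary(),
                               visit_table = "visit_occurrence",
                               concept_column = "visit_concept_id",
                               person_column = "person_id") {
  for (tb in c(visit_table, "person")) {
    if (!table_exists(handle, tb) || row_count(handle, tb) == 0L) {
      warning(sprintf("table '%s' unavailable or empty; visit profile not applicable", tb),
              call. = FALSE)
      return(NULL)
    }
  }
  denom <- data.table::uniqueN(read_table_raw(handle, "person")$person_id)
  visits <- read_table_raw(handle, visit_table)
  dd <- data.table::data.table(
    pid = visits[[tolower(person_column)]],
    category = lookup_concept_name(dictionary, visits[[tolower(concept_column)]]))
  ent <- dd[, list(count = data.table::uniqueN(pid)), by = category]
  data.table::setorder(ent, -count, category)
  new_distribution("visit_type", "persons", ent, denom, multi_membership = TRUE)
}

#' Top concepts ranked by distinct-person coverage
#'
#' Ranks the concepts of a clinical event table by the number of distinct
#' persons having at least one record of that concept, as a percent of all
#' persons. Ties are broken by ascending concept id.
#'
#' @param handle A `dataset_handle`.
#' @param table,concept_column Target table and concept-id column.
#' @param dictionary A [concept_dictionary()].
#' @param n Number of top concepts to return (all if fewer exist).
#' @param person_column Person id column.
#' @return A `category_distribution` (`unit = "persons"`,
#'   `multi_membership = TRUE`).
#' @export
top_concepts_by_person <- function(handle, table, concept_column,
                                   dictionary = default_dictionary(), n = 10L,
                                   person_column = "person_id") {
  table <- tolower(table)
  for (tb in c(table, "person")) {
    if (!table_exists(handle, tb) || row_count(handle, tb) == 0L) {
      warning(sprintf("table '%s' unavailable or empty; top-concept profile not applicable", tb),
              call. = FALSE)
      return(NULL)
    }
  }
  denom <- data.table::uniqueN(read_table_raw(handle, "person")$person_id)
  dt <- read_table_raw(handle, table)
  dd <- data.table::data.table(pid = dt[[tolower(person_column)]],
                               concept_id = trimws(dt[[tolower(concept_column)]]))
  ent <- dd[, list(count = data.table::uniqueN(pid)), by = concept_id]
  ent[, cnum := suppressWarnings(as.numeric(concept_id))]
  data.table::setorder(ent, -count, cnum, concept_id, na.last = TRUE)
  ent <- utils::head(ent, n)
  ent[, category := lookup_concept_name(dictionary, concept_id)]
  out <- ent[, list(category, concept_id, count)]
  new_distribution(paste0("top_concepts:", table), "persons", out, denom,
                   multi_membership = TRUE)
}
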