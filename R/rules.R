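#' @title Declarative completeness rule engine
#' @description Component 2 of the audit: a rulebook of declarative checks
#' evaluated against the dataset. Four rule kinds are supported:
#' `missing_or_special` (missing values and special-character entries),
#' `unmapped_concept` (concept id missing or 0, the reserved "No matching
#' concept" sentinel), `temporal_discontinuity` (>= 100% change between
#' consecutive monthly event counts of a concept), and `value_range`
#' (numeric bound violations). Each result carries a semantic class:
#' a column like `invalid_reason` is NULL by default, so 100% missingness
#' there is *valid by default*, not a completeness deficit.
#' @name rules
NULL

RULE_KINDS <- c("missing_or_special", "unmapped_concept",
                "temporal_discontinuity", "value_range")

#' Default special-value sentinels and special-character class
#'
#' After whitespace trimming, a value counts as "special" when it is empty,
#' equals one of the sentinel strings (case-insensitively), or consists
#' solely of characters from the special-character class. Both sets are
#' overridable per rule.
#' @return Character vector.
#' @export
default_special_values <- function() c("NULL", "NA", "N/A", "UNKNOWN")

#' @rdname default_special_values
#' @export
default_special_chars <- function() c("*", "-", ".", "?", "#", "/", "\\", "+", ",", "_")

special_char_regex <- function(chars) {
  paste0("^[", paste0("\\", chars, collapse = ""), "]+$")
}

#' Declare one completeness rule
#'
#' @param id Unique rule identifier.
#' @param kind One of `missing_or_special`, `unmapped_concept`,
#'   `temporal_discontinuity`, `value_range`.
#' @param table Target table name.
#' @param column Target column (value column, or concept-id column).
#' @param params Kind-specific parameters:
#'   * `missing_or_special`: `special_values`, `special_chars` (defaults:
#'     [default_special_values()], [default_special_chars()]).
#'   * `unmapped_concept`: `unit` (`"persons"` default, or `"rows"`),
#'     `person_column` (default `"person_id"`).
#'   * `temporal_discontinuity`: `date_column` (required), `threshold`
#'     (fractional change, default `1.0`), `insert_zero_months`
#'     (default `TRUE`).
#'   * `value_range`: `bound` (required numeric), `direction` (`"max_le"`
#'     default, or `"min_ge"`), `group_column` (optional concept id column).
#' @param semantic_class `"incompleteness"` (default) or `"expected_null"`
#'   for columns that are NULL by design.
#' @return A `rule_spec`.
#' @export
rule_spec <- function(id, kind, table, column = NULL, params = list(),
                      semantic_class = "incompleteness") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    validation_error("rule id must be a non-empty string")
  if (!kind %in% RULE_KINDS)
    validation_error(sprintf("rule '%s': unknown kind '%s'", id, kind))
  if (!semantic_class %in% c("incompleteness", "expected_null"))
    validation_error(sprintf("rule '%s': unknown semantic_class '%s'", id, semantic_class))
  if (!is.character(table) || !nzchar(table))
    validation_error(sprintf("rule '%s': table is required", id))
  if (kind != "temporal_discontinuity" && (is.null(column) || !nzchar(column)))
    validation_error(sprintf("rule '%s': column is required", id))
  if (kind == "temporal_discontinuity" && is.null(params$date_column))
    validation_error(sprintf("rule '%s': temporal_discontinuity requires params$date_column", id))
  if (kind == "value_range" && (is.null(params$bound) || !is.numeric(params$bound)))
    validation_error(sprintf("rule '%s': value_range requires a numeric params$bound", id))
  if (kind == "value_range" && !is.null(params$direction) &&
      !params$direction %in% c("max_le", "min_ge"))
    validation_error(sprintf("rule '%s': direction must be max_le or min_ge", id))
  if (kind == "unmapped_concept" && !is.null(params$unit) &&
      !params$unit %in% c("rows", "persons"))
    validation_error(sprintf("rule '%s': unit must be rows or persons", id))
  structure(list(id = id, kind = kind, table = tolower(table),
                 column = if (is.null(column)) NULL else tolower(column),
                 params = params, semantic_class = semantic_class),
            class = "rule_spec")
}

new_rule_result <- function(spec_or_id, kind, table, column, flagged, total,
                            semantic_class = "incompleteness", detail = list(),
                            warnings = character(0)) {
  rule_id <- if (inherits(spec_or_id, "rule_spec")) spec_or_id$id else spec_or_id
  interpretation <- if (is.na(total) || total == 0L) {
    "not_applicable"
  } else if (semantic_class == "expected_null") {
    "valid_by_default"
  } else {
    "deficit"
  }
  structure(list(rule_id = rule_id, kind = kind, table = table, column = column,
                 flagged = as.numeric(flagged), total = as.numeric(total),
                 proportion_pct = pct1(flagged, total),
                 semantic_class = semantic_class,
                 interpretation = interpretation,
                 detail = detail, warnings = warnings),
            class = "rule_result")
}

not_applicable_result <- function(id, kind, table, column, semantic_class,
                                  why = "table-not-available") {
  new_rule_result(id, kind, table, column, 0L, 0L, semantic_class,
                  detail = list(reason = why))
}

#' @export
print.rule_result <- function(x, ...) {
  if (x$interpretation == "not_applicable") {
    cat(sprintf("<rule_result> %s: not applicable (%s)\n", x$rule_id,
                x$detail$reason %||% "empty denominator"))
  } else {
    cat(sprintf("<rule_result> %s [%s.%s]: %s/%s (%.1f%%) %s\n", x$rule_id,
                x$table, x$column %||% "-",
                format(x$flagged, big.mark = ","), format(x$total, big.mark = ","),
                x$proportion_pct, x$interpretation))
  }
  invisible(x)
}

#' Flag missing values and special-character entries in one column
#'
#' A record is flagged when its value is missing, or -- after trimming
#' whitespace -- empty, equal (case-insensitively) to a sentinel in
#' `special_values`, or composed solely of characters from `special_chars`.
#' An absent column flags every record (an uncollected column is the
#' strongest form of incompleteness) with warning `column-absent`.
#'
#' @param handle A `dataset_handle`.
#' @param table,column Target table and column.
#' @param special_values Sentinel strings treated as missing.
#' @param special_chars Characters whose pure combinations are special.
#' @param rule_id,semantic_class Carried into the result.
#' @return A `rule_result` with `flagged`, `total` (record count) and a
#'   one-decimal `proportion_pct`; a not-available table yields a
#'   `not_applicable` result, not an error.
#' @export
run_missing_special <- function(handle, table, column,
                                special_values = default_special_values(),
                                special_chars = default_special_chars(),
                                rule_id = paste0(table, ".", column, ".missing_or_special"),
                                semantic_class = "incompleteness") {
  table <- tolower(table); column <- tolower(column)
  if (!table_exists(handle, table))
    return(not_applicable_result(rule_id, "missing_or_special", table, column, semantic_class))
  dt <- read_table_raw(handle, table)
  total <- nrow(dt)
  if (total == 0L)
    return(not_applicable_result(rule_id, "missing_or_special", table, column, semantic_class,
                                 why = "table-empty"))
  warnings <- character(0)
  if (!column %in% names(dt)) {
    warnings <- "column-absent"
    warning(sprintf("column-absent: '%s.%s'; all %d records flagged", table, column, total),
            call. = FALSE)
    return(new_rule_result(rule_id, "missing_or_special", table, column, total, total,
                           semantic_class, detail = list(column_absent = TRUE),
                           warnings = warnings))
  }
  flagged <- sum(flag_missing_special(dt[[column]], special_values, special_chars))
  new_rule_result(rule_id, "missing_or_special", table, column, flagged, total,
                  semantic_class)
}

# vectorized predicate shared with the defect planner
flag_missing_special <- function(x, special_values = default_special_values(),
                                 special_chars = default_special_chars()) {
  v <- trimws(as.character(x))
  out <- is.na(v) | v == ""
  if (length(special_values))
    out <- out | (!is.na(v) & tolower(v) %in% tolower(special_values))
  if (length(special_chars))
    out <- out | (!is.na(v) & grepl(special_char_regex(special_chars), v, perl = TRUE))
  out
}

#' Flag records (or persons) whose concept id is unmapped
#'
#' A record is unmapped when its concept id is missing, non-integer, or `0`
#' (the reserved "No matching concept" sentinel). With `unit = "persons"`
#' the numerator is the number of distinct persons having at least one
#' unmapped record and the denominator the number of distinct persons in
#' the table.
#'
#' @param handle A `dataset_handle`.
#' @param table,concept_column Target table and concept-id column.
#' @param unit `"persons"` (default) or `"rows"`.
#' @param person_column Person id column, used when `unit = "persons"`.
#' @param rule_id,semantic_class Carried into the result.
#' @return A `rule_result`.
#' @export
run_unmapped <- function(handle, table, concept_column, unit = "persons",
                         person_column = "person_id",
                         rule_id = paste0(table, ".", concept_column, ".unmapped"),
                         semantic_class = "incompleteness") {
  table <- tolower(table); concept_column <- tolower(concept_column)
  unit <- match.arg(unit, c("persons", "rows"))
  if (!table_exists(handle, table))
    return(not_applicable_result(rule_id, "unmapped_concept", table, concept_column,
                                 semantic_class))
  dt <- read_table_raw(handle, table)
  if (nrow(dt) == 0L)
    return(not_applicable_result(rule_id, "unmapped_concept", table, concept_column,
                                 semantic_class, why = "table-empty"))
  if (!concept_column %in% names(dt)) {
    warning(sprintf("column-absent: '%s.%s'; all records treated as unmapped",
                    table, concept_column), call. = FALSE)
    unmapped <- rep(TRUE, nrow(dt))
  } else {
    unmapped <- is_unmapped_concept(dt[[concept_column]])
  }
  if (unit == "rows") {
    return(new_rule_result(rule_id, "unmapped_concept", table, concept_column,
                           sum(unmapped), nrow(dt), semantic_class,
                           detail = list(unit = "rows")))
  }
  if (!person_column %in% names(dt))
    validation_error(sprintf("rule '%s': person column '%s' absent from '%s'",
                             rule_id, person_column, table))
  pid <- dt[[person_column]]
  total <- data.table::uniqueN(pid)
  flagged <- data.table::uniqueN(pid[unmapped])
  new_rule_result(rule_id, "unmapped_concept", table, concept_column,
                  flagged, total, semantic_class, detail = list(unit = "persons"))
}

is_unmapped_concept <- function(x) {
  v <- trimws(as.character(x))
  n <- suppressWarnings(as.numeric(v))
  is.na(v) | v == "" | is.na(n) | n == 0
}

#' Detect temporal discontinuities in monthly event counts
#'
#' Events are bucketed by concept and calendar month (ISO dates;
#' non-conforming dates count as missing and are excluded from bucketing).
#' For each concept, consecutive months between its first and last active
#' month are compared, with intervening zero-count months inserted when
#' `insert_zero_months = TRUE` (the default; set `FALSE` to compare only
#' observed months). A concept is flagged when some month-to-month relative
#' change `|c_t - c_(t-1)| / c_(t-1)` (with `c_(t-1) > 0`) reaches
#' `threshold`; a drop to zero is a 100% change and always qualifies at the
#' default threshold. A change from zero to positive is an onset, reported
#' in the detail but never flagged (otherwise every concept's first month
#' would flag).
#'
#' @param handle A `dataset_handle`.
#' @param table,concept_column Target table and concept-id column.
#' @param date_column Event date column.
#' @param threshold Fractional change that flags; default `1.0` (100%).
#' @param insert_zero_months Insert zero-count months inside each concept's
#'   active span before comparing (default `TRUE`).
#' @param rule_id,semantic_class Carried into the result.
#' @return A `rule_result`: `flagged` = number of flagged concepts,
#'   `total` = number of distinct concepts; `detail$flagged_concepts` lists
#'   each flagged concept with its first offending month pair (concept ids
#'   ascending). A wholly unparseable date column yields `not_applicable`.
#' @export
run_temporal_discontinuity <- function(handle, table, concept_column, date_column,
                                       threshold = 1.0, insert_zero_months = TRUE,
                                       rule_id = paste0(table, ".", concept_column, ".temporal"),
                                       semantic_class = "incompleteness") {
  table <- tolower(table)
  concept_column <- tolower(concept_column); date_column <- tolower(date_column)
  if (!table_exists(handle, table))
    return(not_applicable_result(rule_id, "temporal_discontinuity", table,
                                 concept_column, semantic_class))
  dt <- read_table_raw(handle, table)
  if (nrow(dt) == 0L || !all(c(concept_column, date_column) %in% names(dt)))
    return(not_applicable_result(rule_id, "temporal_discontinuity", table,
                                 concept_column, semantic_class, why = "table-empty-or-columns-absent"))
  d <- parse_iso_date(dt[[date_column]])
  ok <- !is.na(d)
  if (!any(ok))
    return(not_applicable_result(rule_id, "temporal_discontinuity", table,
                                 concept_column, semantic_class, why = "dates-unparseable"))
  ev <- data.table::data.table(concept = dt[[concept_column]][ok],
                               mi = month_index(d[ok]))
  counts <- ev[, .N, by = .(concept, mi)]
  data.table::setorder(counts, concept, mi)
  eps <- 1e-9
  assess_one <- function(mi, n) {
    if (insert_zero_months) {
      full <- seq(min(mi), max(mi))
      cnt <- integer(length(full))
      cnt[match(mi, full)] <- n
    } else {
      full <- mi
      cnt <- n
    }
    if (length(cnt) < 2L) return(list(off = NA_integer_, onsets = 0L))
    prev <- cnt[-length(cnt)]
    cur <- cnt[-1L]
    hit <- prev > 0L & (abs(cur - prev) / prev) >= threshold - eps
    onsets <- sum(prev == 0L & cur > 0L)
    j <- which(hit)
    if (length(j) == 0L) return(list(off = NA_integer_, onsets = onsets))
    list(off = full[j[1L] + 1L], prev_mi = full[j[1L]],
         c_prev = prev[j[1L]], c_cur = cur[j[1L]], onsets = onsets)
  }
  per <- counts[, {
    r <- assess_one(mi, N)
    list(off = r$off %||% NA_integer_,
         prev_mi = r$prev_mi %||% NA_integer_,
         c_prev = r$c_prev %||% NA_integer_,
         c_cur = r$c_cur %||% NA_integer_,
         onsets = r$onsets)
  }, by = concept]
  flagged_dt <- per[!is.na(off)]
  cnum <- suppressWarnings(as.numeric(flagged_dt$concept))
  flagged_dt <- flagged_dt[order(cnum, flagged_dt$concept)]
  detail <- list(
    flagged_concepts = data.table::data.table(
      concept_id = flagged_dt$concept,
      month_from = month_label(flagged_dt$prev_mi),
      month_to = month_label(flagged_dt$off),
      count_from = flagged_dt$c_prev,
      count_to = flagged_dt$c_cur),
    n_onsets = sum(per$onsets),
    n_unparseable_dates = sum(!ok))
  new_rule_result(rule_id, "temporal_discontinuity", table, concept_column,
                  nrow(flagged_dt), nrow(per), semantic_class, detail = detail)
}

#' Flag numeric values violating a predefined bound
#'
#' Bounds are strict: under `max_le` a value is flagged when it exceeds the
#' bound (a value equal to the bound passes, per "should not be > bound");
#' under `min_ge`, when it falls below. Non-numeric values are skipped and
#' counted separately in the detail.
#'
#' @param handle A `dataset_handle`.
#' @param table,value_column Target table and numeric column.
#' @param bound Numeric bound.
#' @param direction `"max_le"` (default) or `"min_ge"`.
#' @param group_column Optional concept-id column; the detail then reports
#'   the per-concept maximum (or minimum) among violators, ids ascending.
#' @param rule_id,semantic_class Carried into the result.
#' @return A `rule_result` with `flagged` = violating records and
#'   `total` = record count.
#' @export
run_value_range <- function(handle, table, value_column, bound,
                            direction = "max_le", group_column = NULL,
                            rule_id = paste0(table, ".", value_column, ".range"),
                            semantic_class = "incompleteness") {
  table <- tolower(table); value_column <- tolower(value_column)
  direction <- match.arg(direction, c("max_le", "min_ge"))
  if (!table_exists(handle, table))
    return(not_applicable_result(rule_id, "value_range", table, value_column, semantic_class))
  dt <- read_table_raw(handle, table)
  total <- nrow(dt)
  if (total == 0L || !value_column %in% names(dt))
    return(not_applicable_result(rule_id, "value_range", table, value_column,
                                 semantic_class, why = "table-empty-or-column-absent"))
  v <- suppressWarnings(as.numeric(dt[[value_column]]))
  nonnumeric <- sum(is.na(v) & !is.na(dt[[value_column]]))
  viol <- if (direction == "max_le") !is.na(v) & v > bound else !is.na(v) & v < bound
  detail <- list(n_nonnumeric = nonnumeric, bound = bound, direction = direction)
  if (!is.null(group_column) && tolower(group_column) %in% names(dt) && any(viol)) {
    g <- dt[[tolower(group_column)]][viol]
    vv <- v[viol]
    agg <- data.table::data.table(concept_id = g, value = vv)[
      , if (direction == "max_le") list(extreme = max(value), n = .N)
        else list(extreme = min(value), n = .N), by = concept_id]
    agg <- agg[order(suppressWarnings(as.numeric(concept_id)), concept_id)]
    detail$per_concept <- agg
  }
  new_rule_result(rule_id, "value_range", table, value_column, sum(viol), total,
                  semantic_class, detail = detail)
}

run_rule <- function(handle, spec) {
  stopifnot(inherits(spec, "rule_spec"))
  p <- spec$params
  switch(spec$kind,
    missing_or_special = run_missing_special(
      handle, spec$table, spec$column,
      special_values = p$special_values %||% default_special_values(),
      special_chars = p$special_chars %||% default_special_chars(),
      rule_id = spec$id, semantic_class = spec$semantic_class),
    unmapped_concept = run_unmapped(
      handle, spec$table, spec$column,
      unit = p$unit %||% "persons",
      person_column = p$person_column %||% "person_id",
      rule_id = spec$id, semantic_class = spec$semantic_class),
    temporal_discontinuity = run_temporal_discontinuity(
      handle, spec$table, spec$column %||% p$concept_column,
      date_column = p$date_column,
      threshold = p$threshold %||% 1.0,
      insert_zero_months = p$insert_zero_months %||% TRUE,
      rule_id = spec$id, semantic_class = spec$semantic_class),
    value_range = run_value_range(
      handle, spec$table, spec$column, bound = p$bound,
      direction = p$direction %||% "max_le",
      group_column = p$group_column,
      rule_id = spec$id, semantic_class = spec$semantic_class))
}

#' Evaluate a rulebook against a dataset
#'
#' Rules are evaluated in rulebook order; rules targeting not-available
#' tables yield `not_applicable` results rather than errors. Per-rule wall
#' time is recorded in the `elapsed_s` attribute of each result.
#'
#' @param handle A `dataset_handle`.
#' @param rules A list of [rule_spec()]s (e.g. from [load_rulebook()] or
#'   [default_rulebook()]).
#' @return A `rule_results` list, one `rule_result` per rule, in order.
#'   Convert to a summary table with [as.data.frame()].
#' @export
run_rulebook <- function(handle, rules = default_rulebook()) {
  out <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    t0 <- proc.time()[["elapsed"]]
    res <- run_rule(handle, rules[[i]])
    attr(res, "elapsed_s") <- round(proc.time()[["elapsed"]] - t0, 3)
    out[[i]] <- res
  }
  structure(out, class = "rule_results")
}

#' @export
as.data.frame.rule_results <- function(x, ...) {
  data.frame(
    rule_id = vapply(x, `[[`, "", "rule_id"),
    kind = vapply(x, `[[`, "", "kind"),
    table = vapply(x, `[[`, "", "table"),
    column = vapply(x, function(r) r$column %||% NA_character_, ""),
    flagged = vapply(x, `[[`, 0, "flagged"),
    total = vapply(x, `[[`, 0, "total"),
    pct = vapply(x, function(r) r$proportion_pct %||% NA_real_, 0),
    semantic_class = vapply(x, `[[`, "", "semantic_class"),
    interpretation = vapply(x, `[[`, "", "interpretation"),
    stringsAsFactors = FALSE)
}

#' @export
print.rule_results <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Load a rulebook from a YAML file
#'
#' File layout:
#' ```yaml
#' rules:
#'   - id: vocabulary.version.missing
#'     kind: missing_or_special
#'     table: vocabulary
#'     column: vocabulary_version
#'     semantic_class: incompleteness
#'     params: {}
#' ```
#'
#' @param path Path to the rulebook file.
#' @return A list of validated [rule_spec()]s (class `rulebook`).
#' @export
load_rulebook <- function(path) {
  if (!file.exists(path)) data_error(sprintf("rulebook file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) validation_error(
                    sprintf("malformed rulebook '%s': %s", path, conditionMessage(e))))
  if (is.null(doc$rules)) validation_error(sprintf("rulebook '%s' has no 'rules' entry", path))
  rules <- lapply(doc$rules, function(r) {
    rule_spec(r$id %||% validation_error("rulebook entry missing 'id'"),
              r$kind %||% "", r$table %||% "", r$column,
              params = r$params %||% list(),
              semantic_class = r$semantic_class %||% "incompleteness")
  })
  ids <- vapply(rules, `[[`, "", "id")
  if (anyDuplicated(ids))
    validation_error(sprintf("duplicate rule id(s): %s",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(rules, class = "rulebook")
}

#' The bundled default rulebook
#'
#' Reconstructs the audit's standard checks: 11 missing/special-value
#' table-column pairs (with the two `invalid_reason` columns tagged
#' `expected_null`), per-domain unmapped-concept checks counted in persons,
#' per-domain monthly-count discontinuity checks at the 100% threshold, and
#' the two prescription value-range checks (`days_supply` <= 180,
#' `quantity` <= 600). Fully user-replaceable via [load_rulebook()].
#'
#' @return A `rulebook`.
#' @export
default_rulebook <- function() {
  load_rulebook(system.file("extdata", "default-rulebook.yaml",
                            package = "cdmaudit", mustWork = TRUE))
}
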