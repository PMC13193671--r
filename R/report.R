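#' @title Completeness report assembly and rendering
#' @description Aggregates the three audit components into a single report
#' with interpreted findings, and renders it as lossless schema-versioned
#' JSON, human-readable Markdown, or a CSV bundle. Issue detection alone is
#' not an assessment: each finding carries a machine-readable code and an
#' interpretation sentence, and expected-null rule results never raise
#' deficit findings however high their missingness.
#' @name report
NULL

REPORT_SCHEMA_VERSION <- "1.0.0"

#' Assemble a completeness report
#'
#' Any subset of the three components may be supplied; absent components
#' are recorded as skipped. Findings are ordered deterministically:
#' severity (deficit, warning, info) then code then detail.
#'
#' @param structural A `structural_report` or `NULL`.
#' @param rule_results A `rule_results` list or `NULL`.
#' @param profiles Named list of `category_distribution`s or `NULL`.
#' @param metadata Named list of run metadata (dataset locator, manifest /
#'   rulebook identifiers, seed); tool version and a UTC timestamp are
#'   added automatically.
#' @param severity_threshold_pct Minimum flagged proportion (percent) for
#'   an incompleteness-class rule to raise a deficit finding (default 5).
#' @return A `completeness_report`.
#' @export
assemble_report <- function(structural = NULL, rule_results = NULL,
                            profiles = NULL, metadata = list(),
                            severity_threshold_pct = 5) {
  findings <- list()
  add <- function(severity, code, message) {
    findings[[length(findings) + 1L]] <<- list(severity = severity, code = code,
                                               message = message)
  }
  if (!is.null(structural)) {
    pt <- structural$per_table
    for (i in which(pt$note == "free-text-capture-gap"))
      add("warning", "free-text-capture-gap", sprintf(
        "table '%s' is not available: clinical free-text narratives were not captured",
        pt$table[i]))
    for (i in which(pt$note == "derived-table-not-populated"))
      add("info", "derived-table-not-populated", sprintf(
        "table '%s' is empty: the ETL derivation scripts were most likely not executed",
        pt$table[i]))
    for (i in which(pt$status == "not_available" & pt$note == "none"))
      add("warning", "table-not-available", sprintf("table '%s' is not available", pt$table[i]))
    for (i in which(pt$status == "empty" & pt$note == "none"))
      add("info", "table-empty", sprintf("table '%s' is present but holds no records", pt$table[i]))
  }
  if (!is.null(rule_results)) {
    for (r in rule_results) {
      if (r$interpretation == "deficit" && r$semantic_class == "incompleteness" &&
          !is.na(r$proportion_pct) && r$proportion_pct >= severity_threshold_pct) {
        add("deficit", "rule-deficit", sprintf(
          "%s: %s/%s records flagged (%.1f%%) in %s.%s",
          r$rule_id, format(r$flagged, big.mark = ","),
          format(r$total, big.mark = ","), r$proportion_pct, r$table,
          r$column %||% ""))
      }
      if (r$interpretation == "valid_by_default") {
        add("info", "valid-by-default", sprintf(
          "%s: %.1f%% flagged, but the column is NULL by default; this is valid data, not incompleteness",
          r$rule_id, r$proportion_pct))
      }
    }
  }
  sev_rank <- c(deficit = 1L, warning = 2L, info = 3L)
  ord <- order(sev_rank[vapply(findings, `[[`, "", "severity")],
               vapply(findings, `[[`, "", "code"),
               vapply(findings, `[[`, "", "message"))
  metadata$tool <- "cdmaudit"
  metadata$tool_version <- as.character(utils::packageVersion("cdmaudit"))
  metadata$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    metadata = metadata,
    structural = structural,
    rule_results = rule_results,
    profiles = profiles,
    skipped = c("structural", "rules", "profiles")[c(is.null(structural),
                                                     is.null(rule_results),
                                                     is.null(profiles))],
    findings = findings[ord]), class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("<completeness_report> schema %s, %d finding(s)\n",
              x$schema_version, length(x$findings)))
  for (f in x$findings[seq_len(min(10, length(x$findings)))])
    cat(sprintf("  [%s] %s: %s\n", f$severity, f$code, f$message))
  if (length(x$findings) > 10) cat("  ...\n")
  invisible(x)
}

report_to_list <- function(report) {
  s <- report$structural
  list(
    schema_version = report$schema_version,
    metadata = report$metadata,
    skipped = as.list(report$skipped),
    structural = if (!is.null(s)) list(
      per_table = s$per_table,
      n_tables = s$n_tables, n_available = s$n_available,
      n_empty = s$n_empty, n_not_available = s$n_not_available,
      pct_empty = s$pct_empty, pct_not_available = s$pct_not_available,
      total_rows = s$total_rows, unexpected_tables = as.list(s$unexpected_tables)),
    rules = if (!is.null(report$rule_results)) lapply(report$rule_results, function(r)
      list(rule_id = r$rule_id, kind = r$kind, table = r$table,
           column = r$column, flagged = r$flagged, total = r$total,
           proportion_pct = r$proportion_pct, semantic_class = r$semantic_class,
           interpretation = r$interpretation,
           detail = rule_detail_to_list(r$detail))),
    profiles = if (!is.null(report$profiles)) lapply(report$profiles, function(p)
      list(dimension = p$dimension, unit = p$unit, denominator = p$denominator,
           multi_membership = p$multi_membership, entries = p$entries)),
    findings = report$findings)
}

rule_detail_to_list <- function(detail) {
  lapply(detail, function(d) if (data.table::is.data.table(d)) d else d)
}

#' Render a completeness report to files
#'
#' @param report A `completeness_report`.
#' @param format `"json"` (lossless, schema-versioned), `"markdown"`
#'   (structural, then rules, then profiles), or `"csv_bundle"` (one CSV
#'   per component).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths.
#' @export
render_report <- function(report, format = c("json", "markdown", "csv_bundle"),
                          out_dir = ".") {
  stopifnot(inherits(report, "completeness_report"))
  if (length(format) != 1L || !format %in% c("json", "markdown", "csv_bundle"))
    usage_error(sprintf("unknown report format '%s'", paste(format, collapse = ",")))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "json") {
    path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null", pretty = TRUE)
    return(path)
  }
  if (format == "markdown") {
    path <- file.path(out_dir, "report.md")
    writeLines(render_markdown(report), path)
    return(path)
  }
  paths <- character(0)
  if (!is.null(report$structural)) {
    p <- file.path(out_dir, "structural.csv")
    data.table::fwrite(report$structural$per_table, p)
    paths <- c(paths, p)
  }
  if (!is.null(report$rule_results)) {
    p <- file.path(out_dir, "rules.csv")
    data.table::fwrite(as.data.frame(report$rule_results), p)
    paths <- c(paths, p)
  }
  if (!is.null(report$profiles)) {
    p <- file.path(out_dir, "profiles.csv")
    prof <- data.table::rbindlist(lapply(report$profiles, function(pp)
      data.table::data.table(dimension = pp$dimension, unit = pp$unit,
                             category = pp$entries$category,
                             count = pp$entries$count,
                             percent = pp$entries$percent,
                             denominator = pp$denominator)), fill = TRUE)
    data.table::fwrite(prof, p)
    paths <- c(paths, p)
  }
  fp <- file.path(out_dir, "findings.csv")
  data.table::fwrite(data.table::rbindlist(lapply(report$findings, data.table::as.data.table)), fp)
  c(paths, fp)
}

render_markdown <- function(report) {
  out <- c("# Completeness audit report", "",
           sprintf("Generated by %s %s at %s.",
                   report$metadata$tool, report$metadata$tool_version,
                   report$metadata$timestamp), "")
  s <- report$structural
  if (!is.null(s)) {
    out <- c(out, "## Structural completeness", "",
             sprintf("%d expected tables: %d available, %d empty (%.1f%%), %d not available (%.1f%%); %s records in available tables.",
                     s$n_tables, s$n_available, s$n_empty, s$pct_empty,
                     s$n_not_available, s$pct_not_available,
                     format(s$total_rows, big.mark = ",", scientific = FALSE)), "",
             "| Table | Status | Rows | Note |", "|---|---|---:|---|",
             sprintf("| %s | %s | %s | %s |", s$per_table$table, s$per_table$status,
                     ifelse(is.na(s$per_table$rows), "", format(s$per_table$rows, big.mark = ",")),
                     s$per_table$note), "")
  }
  rr <- report$rule_results
  if (!is.null(rr)) {
    df <- as.data.frame(rr)
    out <- c(out, "## Rule-based completeness", "",
             "| Rule | Table | Column | Flagged | Total | % | Interpretation |",
             "|---|---|---|---:|---:|---:|---|",
             sprintf("| %s | %s | %s | %s | %s | %s | %s |", df$rule_id, df$table,
                     ifelse(is.na(df$column), "", df$column),
                     format(df$flagged, big.mark = ","), format(df$total, big.mark = ","),
                     ifelse(is.na(df$pct), "", sprintf("%.1f", df$pct)),
                     df$interpretation), "")
  }
  if (!is.null(report$profiles)) {
    out <- c(out, "## Completeness and diversity profiles", "")
    for (p in report$profiles) {
      out <- c(out, sprintf("### %s (unit: %s, n = %s)", p$dimension, p$unit,
                            format(p$denominator, big.mark = ",")),
               "", "| Category | Count | % |", "|---|---:|---:|",
               sprintf("| %s | %s | %.1f |", p$entries$category,
                       format(p$entries$count, big.mark = ","), p$entries$percent), "")
    }
  }
  out <- c(out, "## Findings", "")
  if (length(report$findings) == 0L) out <- c(out, "No findings.")
  for (f in report$findings)
    out <- c(out, sprintf("- **%s** `%s`: %s", f$severity, f$code, f$message))
  out
}

#' Reload a JSON report
#'
#' @param path Path written by `render_report(..., format = "json")`.
#' @return The parsed report list. A major schema version mismatch is an
#'   error.
#' @export
load_report <- function(path) {
  if (!file.exists(path)) data_error(sprintf("report file not found: %s", path))
  rep <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- rep$schema_version %||% ""
  if (!identical(sub("\\..*$", "", ver), sub("\\..*$", "", REPORT_SCHEMA_VERSION)))
    validation_error(sprintf("report schema major version mismatch: file has '%s', tool supports '%s'",
                             ver, REPORT_SCHEMA_VERSION))
  rep
}

#' Run the full three-component audit
#'
#' Convenience wrapper: structural report, default (or given) rulebook, and
#' the standard profile set (demographics, visit types, top condition /
#' drug / measurement concepts by person, vocabulary distributions for the
#' four major domains).
#'
#' @param handle A `dataset_handle`.
#' @param manifest A [schema_manifest()].
#' @param rulebook A rulebook (list of [rule_spec()]s).
#' @param dictionary A [concept_dictionary()].
#' @param metadata Extra metadata stored in the report.
#' @return A `completeness_report`.
#' @export
run_audit <- function(handle, manifest = default_manifest(),
                      rulebook = default_rulebook(),
                      dictionary = default_dictionary(), metadata = list()) {
  structural <- structural_report(handle, manifest)
  rules <- run_rulebook(handle, rulebook)
  profiles <- suppressWarnings(c(
    demographic_profile(handle, dictionary),
    list(visit_type = visit_type_profile(handle, dictionary)),
    list(top_conditions = top_concepts_by_person(handle, "condition_occurrence",
                                                 "condition_concept_id", dictionary, n = 10)),
    list(top_drugs = top_concepts_by_person(handle, "drug_exposure",
                                            "drug_concept_id", dictionary, n = 10)),
    list(top_measurements = top_concepts_by_person(handle, "measurement",
                                                   "measurement_concept_id", dictionary, n = 10)),
    list(vocab_measurement = vocabulary_distribution(handle, "measurement",
                                                     "measurement_concept_id", dictionary)),
    list(vocab_drug = vocabulary_distribution(handle, "drug_exposure",
                                              "drug_concept_id", dictionary)),
    list(vocab_observation = vocabulary_distribution(handle, "observation",
                                                     "observation_concept_id", dictionary)),
    list(vocab_procedure = vocabulary_distribution(handle, "procedure_occurrence",
                                                   "procedure_concept_id", dictionary))))
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]
  metadata$dataset <- handle$locator
  metadata$dialect <- handle$dialect
  assemble_report(structural, rules, profiles, metadata)
}
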