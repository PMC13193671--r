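#' @title Structural completeness assessment
#' @description Component 1 of the audit: classify every expected table as
#' available / empty / not available, count records, and profile storage
#' volume. Percentages are rounded half-up to one decimal.
#' @name structural
NULL

#' Classify the availability of one expected table
#'
#' @param handle A `dataset_handle`.
#' @param spec A [table_spec()] (or a table name).
#' @return `"not_available"` if the table cannot be queried, `"empty"` if it
#'   is queryable with zero records, `"available"` otherwise.
#' @export
classify_table <- function(handle, spec) {
  nm <- if (inherits(spec, "table_spec")) spec$name else tolower(spec)
  if (!table_exists(handle, nm)) return("not_available")
  if (row_count(handle, nm) == 0L) return("empty")
  "available"
}

#' Structural report over a full manifest
#'
#' Classifies every manifest table, aggregates availability counts and the
#' dataset-wide record total, and annotates interpretable findings
#' (see [annotate_interpretation()]). Tables present in the dataset but not
#' in the manifest are listed separately as unexpected, not classified.
#'
#' @param handle A `dataset_handle`.
#' @param manifest A [schema_manifest()]; defaults to the bundled 39-table
#'   CDM v5.3 manifest.
#' @return A `structural_report`: `per_table` (data.table with `table`,
#'   `status`, `rows`, `bytes`, `note`), availability counts, one-decimal
#'   `pct_empty` / `pct_not_available`, `total_rows` over available tables,
#'   and `unexpected_tables`.
#' @export
structural_report <- function(handle, manifest = default_manifest()) {
  stopifnot(inherits(manifest, "schema_manifest"))
  nms <- manifest_table_names(manifest)
  status <- character(length(nms))
  rows <- rep(NA_integer_, length(nms))
  bytes <- rep(NA_real_, length(nms))
  for (i in seq_along(nms)) {
    st <- classify_table(handle, nms[[i]])
    status[[i]] <- st
    if (st != "not_available") {
      rows[[i]] <- row_count(handle, nms[[i]])
      bytes[[i]] <- table_bytes(handle, nms[[i]])
    }
  }
  per_table <- data.table::data.table(table = nms, status = status,
                                      rows = rows, bytes = bytes,
                                      note = "none")
  n_tables <- length(nms)
  n_available <- sum(status == "available")
  n_empty <- sum(status == "empty")
  n_not_available <- sum(status == "not_available")
  rep <- structure(list(
    per_table = per_table,
    n_tables = n_tables,
    n_available = n_available,
    n_empty = n_empty,
    n_not_available = n_not_available,
    pct_empty = pct1(n_empty, n_tables),
    pct_not_available = pct1(n_not_available, n_tables),
    total_rows = sum(as.numeric(rows[status == "available"])),
    unexpected_tables = setdiff(list_tables(handle), nms)
  ), class = "structural_report")
  annotate_interpretation(rep, manifest)
}

#' Attach interpretation notes to a structural report
#'
#' Encodes the two context-dependent readings of structural findings:
#' an empty ETL-derived table most likely means the derivation scripts were
#' not executed (`derived-table-not-populated`), and an absent free-text
#' table means clinical narratives were never captured
#' (`free-text-capture-gap`). All other findings carry note `"none"`.
#'
#' @param report A `structural_report`.
#' @param manifest The manifest the report was computed against.
#' @return The report with its `per_table$note` column filled in.
#' @export
annotate_interpretation <- function(report, manifest = default_manifest()) {
  stopifnot(inherits(report, "structural_report"))
  pt <- report$per_table
  derived <- vapply(manifest$tables, `[[`, TRUE, "derived")
  freetext <- vapply(manifest$tables, `[[`, TRUE, "holds_free_text")
  idx <- match(pt$table, manifest_table_names(manifest))
  new_note <- rep("none", nrow(pt))
  new_note[pt$status == "empty" & derived[idx] %in% TRUE] <- "derived-table-not-populated"
  new_note[pt$status == "not_available" & freetext[idx] %in% TRUE] <- "free-text-capture-gap"
  pt[, note := new_note]
  report$per_table <- pt
  report
}

#' Volume profile of available tables
#'
#' @param handle A `dataset_handle`.
#' @param manifest A [schema_manifest()].
#' @return data.table (`table`, `bytes`, `fraction`) over available tables,
#'   ordered by descending bytes; fractions sum to 1. Empty and absent
#'   tables are excluded. With the SQL dialect, bytes are approximate and
#'   fractions are `NA` when the engine does not report sizes.
#' @export
volume_profile <- function(handle, manifest = default_manifest()) {
  stopifnot(inherits(manifest, "schema_manifest"))
  nms <- manifest_table_names(manifest)
  avail <- nms[vapply(nms, function(nm) classify_table(handle, nm) == "available", TRUE)]
  b <- vapply(avail, function(nm) table_bytes(handle, nm), 0)
  out <- data.table::data.table(table = avail, bytes = as.numeric(b))
  data.table::setorder(out, -bytes, table)
  tot <- sum(out$bytes)
  out[, fraction := if (anyNA(bytes) || tot <= 0) NA_real_ else bytes / tot]
  out[]
}

#' @export
print.structural_report <- function(x, ...) {
  cat(sprintf("<structural_report> %d tables: %d available, %d empty (%.1f%%), %d not available (%.1f%%)\n",
              x$n_tables, x$n_available, x$n_empty, x$pct_empty,
              x$n_not_available, x$pct_not_available))
  cat(sprintf("  total records in available tables: %s\n",
              format(x$total_rows, big.mark = ",", scientific = FALSE)))
  if (length(x$unexpected_tables))
    cat("  unexpected tables:", paste(x$unexpected_tables, collapse = ", "), "\n")
  invisible(x)
}
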