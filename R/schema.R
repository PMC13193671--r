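#' @title Schema manifests
#' @description A schema manifest declares which tables (and which columns,
#' with semantic roles) a dataset is expected to contain. Every assessment
#' component reads the dataset through the manifest, so the same audit runs
#' unchanged against any CDM-like layout the manifest can describe.
#' @name schema
NULL

COLUMN_ROLES <- c("row_id", "person_id", "concept_id", "source_value", "date",
                  "datetime", "numeric_value", "text_value", "code", "other")

#' Declare a column of an expected table
#'
#' @param name Column name (matched case-insensitively against data).
#' @param role Semantic role, one of `row_id`, `person_id`, `concept_id`,
#'   `source_value`, `date`, `datetime`, `numeric_value`, `text_value`,
#'   `code`, `other`.
#' @param nullable Whether missing values are structurally permitted.
#' @return A `column_spec` object.
#' @export
column_spec <- function(name, role = "other", nullable = TRUE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    validation_error("column name must be a non-empty string")
  if (!role %in% COLUMN_ROLES)
    validation_error(sprintf("column '%s': unknown role '%s'", name, role))
  structure(list(name = tolower(name), role = role, nullable = isTRUE(nullable)),
            class = "column_spec")
}

#' Declare an expected table
#'
#' @param name Table name.
#' @param columns List of [column_spec()] objects (at least one).
#' @param derived `TRUE` for tables populated by ETL derivation scripts
#'   (e.g. `dose_era`); an empty derived table is interpreted as
#'   "derivation not executed" rather than missing source data.
#' @param holds_free_text `TRUE` for tables designed to hold clinical
#'   free-text narratives (`note`, `note_nlp`); their absence is flagged as
#'   a free-text capture gap.
#' @return A `table_spec` object.
#' @export
table_spec <- function(name, columns, derived = FALSE, holds_free_text = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    validation_error("table name must be a non-empty string")
  if (length(columns) < 1L)
    validation_error(sprintf("table '%s' must declare at least one column", name))
  columns <- lapply(columns, function(cl) {
    if (inherits(cl, "column_spec")) cl else do.call(column_spec, cl)
  })
  cn <- vapply(columns, `[[`, "", "name")
  if (anyDuplicated(cn))
    validation_error(sprintf("table '%s': duplicate column name(s): %s", name,
                             paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  structure(list(name = tolower(name), columns = columns,
                 derived = isTRUE(derived), holds_free_text = isTRUE(holds_free_text)),
            class = "table_spec")
}

#' Assemble a schema manifest
#'
#' @param tables List of [table_spec()] objects; names must be unique.
#' @param version_label Free-text label for the schema version.
#' @return A `schema_manifest` object.
#' @export
schema_manifest <- function(tables, version_label = "") {
  tables <- lapply(tables, function(tb) {
    if (inherits(tb, "table_spec")) tb else do.call(table_spec, tb)
  })
  nm <- vapply(tables, `[[`, "", "name")
  if (anyDuplicated(nm))
    validation_error(sprintf("duplicate table name(s) in manifest: %s",
                             paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  names(tables) <- nm
  structure(list(tables = tables, version_label = as.character(version_label)),
            class = "schema_manifest")
}

#' @export
print.schema_manifest <- function(x, ...) {
  cat(sprintf("<schema_manifest> %d tables (version '%s')\n",
              length(x$tables), x$version_label))
  invisible(x)
}

#' @export
length.schema_manifest <- function(x) length(x$tables)

manifest_table_names <- function(manifest) names(manifest$tables)

#' Load a schema manifest from a YAML file
#'
#' The file layout is:
#' ```yaml
#' version_label: "CDM v5.3"
#' tables:
#'   - name: person
#'     derived: false
#'     holds_free_text: false
#'     columns:
#'       - {name: person_id, role: row_id, nullable: false}
#' ```
#'
#' @param path Path to the manifest file.
#' @return A validated [schema_manifest()].
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) data_error(sprintf("manifest file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) validation_error(
                    sprintf("malformed manifest '%s': %s", path, conditionMessage(e))))
  if (is.null(doc$tables)) validation_error(sprintf("manifest '%s' has no 'tables' entry", path))
  tabs <- lapply(doc$tables, function(tb) {
    cols <- lapply(tb$columns, function(cl)
      column_spec(cl$name, cl$role %||% "other", cl$nullable %||% TRUE))
    table_spec(tb$name, cols, derived = tb$derived %||% FALSE,
               holds_free_text = tb$holds_free_text %||% FALSE)
  })
  schema_manifest(tabs, version_label = doc$version_label %||% "")
}

#' The bundled 39-table CDM v5.3-style manifest
#'
#' Covers the standard clinical event, vocabulary, era, cohort and metadata
#' tables of OMOP CDM v5.3. It is the default expected schema for audits and
#' is fully user-replaceable via [load_manifest()].
#'
#' @return A [schema_manifest()] with 39 tables.
#' @export
default_manifest <- function() {
  load_manifest(system.file("extdata", "cdm-v5.3-manifest.yaml",
                            package = "cdmaudit", mustWork = TRUE))
}
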