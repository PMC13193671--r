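#' @title Dataset access layer
#' @description Uniform read access to a CDM-like dataset stored either as a
#' directory of RFC-4180 delimited files (`<table>.csv`, header row, empty
#' unquoted field = missing) or as a single-file SQLite database (one
#' relation per table). All assessment components operate through this
#' layer, so results are independent of the storage dialect; the only
#' documented exception is [table_bytes()], whose SQL value is the
#' engine-reported (approximate) relation size.
#' @name dataset
NULL

DIALECTS <- c("delimited_directory", "sql_database")

#' Open a dataset for auditing
#'
#' @param locator Directory path (delimited dialect) or SQLite file path.
#' @param dialect `"delimited_directory"` or `"sql_database"`; inferred from
#'   the locator (directory vs file) when omitted.
#' @return A `dataset_handle`. Close SQL handles with [close_dataset()]
#'   when done (also registered as a finalizer).
#' @export
open_dataset <- function(locator, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (dir.exists(locator)) "delimited_directory" else "sql_database"
  }
  dialect <- match.arg(dialect, DIALECTS)
  if (dialect == "delimited_directory") {
    if (!dir.exists(locator))
      data_error(sprintf("cannot open dataset: directory not found or unreadable: %s", locator))
  } else {
    if (!file.exists(locator))
      data_error(sprintf("cannot open dataset: database file not found: %s", locator))
  }
  h <- new.env(parent = emptyenv())
  h$locator <- normalizePath(locator)
  h$dialect <- dialect
  h$cache_name <- NULL
  h$cache_table <- NULL
  if (dialect == "sql_database") {
    h$con <- DBI::dbConnect(RSQLite::SQLite(), locator)
    reg.finalizer(h, function(e) {
      if (!is.null(e$con) && DBI::dbIsValid(e$con)) DBI::dbDisconnect(e$con)
    }, onexit = TRUE)
  }
  class(h) <- "dataset_handle"
  h
}

#' Close a dataset handle
#' @param handle A `dataset_handle`.
#' @return Invisibly `NULL`.
#' @export
close_dataset <- function(handle) {
  stopifnot(inherits(handle, "dataset_handle"))
  if (!is.null(handle$con) && DBI::dbIsValid(handle$con)) DBI::dbDisconnect(handle$con)
  handle$cache_name <- NULL
  handle$cache_table <- NULL
  invisible(NULL)
}

#' @export
print.dataset_handle <- function(x, ...) {
  cat(sprintf("<dataset_handle> dialect=%s locator=%s\n", x$dialect, x$locator))
  invisible(x)
}

delim_path <- function(handle, table_name) {
  file.path(handle$locator, paste0(tolower(table_name), ".csv"))
}

#' Does a table exist in the dataset?
#'
#' Absence is a value, not an error: an expected table that cannot be
#' queried is classified "not available" by the structural assessment.
#'
#' @param handle A `dataset_handle`.
#' @param table_name Table name.
#' @return `TRUE` iff the table can be queried (file present / relation
#'   present), even when it holds zero records.
#' @export
table_exists <- function(handle, table_name) {
  stopifnot(inherits(handle, "dataset_handle"))
  if (handle$dialect == "delimited_directory") {
    file.exists(delim_path(handle, table_name))
  } else {
    tolower(table_name) %in% tolower(DBI::dbListTables(handle$con))
  }
}

#' List all tables present in the dataset
#' @param handle A `dataset_handle`.
#' @return Character vector of table names (lower case).
#' @export
list_tables <- function(handle) {
  stopifnot(inherits(handle, "dataset_handle"))
  if (handle$dialect == "delimited_directory") {
    f <- list.files(handle$locator, pattern = "\\.csv$")
    sort(tolower(sub("\\.csv$", "", f)))
  } else {
    sort(tolower(DBI::dbListTables(handle$con)))
  }
}

# read the full table as an all-character data.table with NA as the single
# missing sentinel; headers lowered; most recent table cached on the handle
read_table_raw <- function(handle, table_name) {
  table_name <- tolower(table_name)
  if (identical(handle$cache_name, table_name)) return(handle$cache_table)
  if (!table_exists(handle, table_name)) not_available_error(table_name)
  if (handle$dialect == "delimited_directory") {
    dt <- data.table::fread(delim_path(handle, table_name), header = TRUE,
                            colClasses = "character", na.strings = "",
                            showProgress = FALSE)
  } else {
    df <- DBI::dbReadTable(handle$con, sql_table_name(handle, table_name))
    dt <- data.table::as.data.table(df)
    for (j in seq_along(dt)) {
      v <- as.character(dt[[j]])
      v[!is.na(v) & v == ""] <- NA_character_
      data.table::set(dt, j = j, value = v)
    }
  }
  data.table::setnames(dt, tolower(names(dt)))
  handle$cache_name <- table_name
  handle$cache_table <- dt
  dt
}

sql_table_name <- function(handle, table_name) {
  tabs <- DBI::dbListTables(handle$con)
  hit <- tabs[tolower(tabs) == tolower(table_name)]
  if (length(hit) == 0L) not_available_error(table_name)
  hit[[1L]]
}

#' Read a table through the uniform missing-value contract
#'
#' Values are returned as character columns with a single missing sentinel
#' (`NA`): a database `NULL` and an empty delimited field are
#' indistinguishable downstream. Column headers are matched
#' case-insensitively.
#'
#' @param handle A `dataset_handle`.
#' @param table_name Table name (must exist; see [table_exists()]).
#' @param columns Optional character vector of columns to return. Requested
#'   columns absent from the stored table are surfaced as all-missing
#'   columns with a warning (`column-absent`).
#' @return A `data.table` of records.
#' @export
read_table <- function(handle, table_name, columns = NULL) {
  dt <- read_table_raw(handle, table_name)
  if (is.null(columns)) return(data.table::copy(dt))
  columns <- tolower(columns)
  missing_cols <- setdiff(columns, names(dt))
  out <- dt[, intersect(columns, names(dt)), with = FALSE]
  for (mc in missing_cols) {
    warning(sprintf("column-absent: '%s.%s' not present in stored table; returned all-missing",
                    tolower(table_name), mc), call. = FALSE)
    out[, (mc) := NA_character_]
  }
  data.table::setcolorder(out, columns)
  out
}

#' Exact record count of a table
#' @param handle A `dataset_handle`.
#' @param table_name Table name (must exist).
#' @return Nonnegative integer record count.
#' @export
row_count <- function(handle, table_name) {
  table_name <- tolower(table_name)
  if (!table_exists(handle, table_name)) not_available_error(table_name)
  if (identical(handle$cache_name, table_name)) return(nrow(handle$cache_table))
  if (handle$dialect == "delimited_directory") {
    p <- delim_path(handle, table_name)
    if (file.size(p) == 0L) return(0L)
    nrow(data.table::fread(p, header = TRUE, select = 1L,
                           colClasses = "character", showProgress = FALSE))
  } else {
    as.integer(DBI::dbGetQuery(handle$con, sprintf(
      "SELECT COUNT(*) AS n FROM \"%s\"", sql_table_name(handle, table_name)))$n)
  }
}

#' Storage size of a table in bytes
#'
#' For the delimited dialect this is the exact file size. For the SQL
#' dialect it is the engine-reported relation size (SQLite `dbstat`), which
#' is approximate and may be `NA` when the engine does not expose it;
#' volume profiles are therefore only comparable within one dialect.
#'
#' @param handle A `dataset_handle`.
#' @param table_name Table name (must exist).
#' @return Number of bytes, or `NA` when unavailable (SQL dialect only).
#' @export
table_bytes <- function(handle, table_name) {
  if (!table_exists(handle, table_name)) not_available_error(table_name)
  if (handle$dialect == "delimited_directory") {
    as.numeric(file.size(delim_path(handle, table_name)))
  } else {
    out <- tryCatch(
      DBI::dbGetQuery(handle$con, sprintf(
        "SELECT SUM(pgsize) AS b FROM dbstat WHERE name = '%s'",
        sql_table_name(handle, table_name)))$b,
      error = function(e) NA_real_)
    as.numeric(out %||% NA_real_)
  }
}

#' Write a set of tables as a dataset
#'
#' Writer used by the synthetic generator and by round-trip tests. Missing
#' values are written as empty fields (delimited) or SQL `NULL`.
#'
#' @param tables Named list of data.frames/data.tables.
#' @param locator Target directory (delimited) or SQLite file path.
#' @param dialect Storage dialect.
#' @return The locator, invisibly.
#' @export
write_dataset <- function(tables, locator, dialect = "delimited_directory") {
  dialect <- match.arg(dialect, DIALECTS)
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (dialect == "delimited_directory") {
    dir.create(locator, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      data.table::fwrite(tables[[nm]], file.path(locator, paste0(tolower(nm), ".csv")),
                         na = "", quote = "auto")
    }
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), locator)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    for (nm in names(tables)) {
      df <- as.data.frame(tables[[nm]])
      df[] <- lapply(df, as.character)
      DBI::dbWriteTable(con, tolower(nm), df, overwrite = TRUE)
    }
  }
  invisible(locator)
}

# in-place single-table writer for the defect injector
write_table_inplace <- function(locator, dialect, table_name, dt) {
  if (dialect == "delimited_directory") {
    data.table::fwrite(dt, file.path(locator, paste0(tolower(table_name), ".csv")),
                       na = "", quote = "auto")
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), locator)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    df <- as.data.frame(dt)
    df[] <- lapply(df, as.character)
    DBI::dbWriteTable(con, tolower(table_name), df, overwrite = TRUE)
  }
  invisible(NULL)
}

drop_table_inplace <- function(locator, dialect, table_name) {
  if (dialect == "delimited_directory") {
    unlink(file.path(locator, paste0(tolower(table_name), ".csv")))
  } else {
    con <- DBI::dbConnect(RSQLite::SQLite(), locator)
    on.exit(DBI::dbDisconnect(con), add = TRUE)
    DBI::dbExecute(con, sprintf("DROP TABLE IF EXISTS \"%s\"", tolower(table_name)))
  }
  invisible(NULL)
}
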