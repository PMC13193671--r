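# Brute-force oracles, written independently of the rule engine: explicit
# per-record loops, base-R only. Used to cross-check every rule and profile
# on small tables.

oracle_missing_special <- function(values,
                                   sentinels = c("NULL", "NA", "N/A", "UNKNOWN"),
                                   chars = c("*", "-", ".", "?", "#", "/", "\\", "+", ",", "_")) {
  n <- 0L
  for (v in values) {
    if (is.na(v)) { n <- n + 1L; next }
    t <- gsub("^[[:space:]]+|[[:space:]]+$", "", v)
    if (nchar(t) == 0L) { n <- n + 1L; next }
    if (toupper(t) %in% toupper(sentinels)) { n <- n + 1L; next }
    if (all(strsplit(t, "")[[1]] %in% chars)) n <- n + 1L
  }
  n
}

oracle_unmapped_rows <- function(ids) {
  n <- 0L
  for (v in ids) {
    if (is.na(v)) { n <- n + 1L; next }
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num) || num == 0) n <- n + 1L
  }
  n
}

oracle_unmapped_persons <- function(ids, persons) {
  flagged <- character(0)
  for (i in seq_along(ids)) {
    v <- ids[[i]]
    num <- suppressWarnings(as.numeric(v))
    if (is.na(v) || is.na(num) || num == 0) flagged <- union(flagged, persons[[i]])
  }
  c(flagged = length(flagged), total = length(unique(persons)))
}

# flagged concepts from scratch: tabulate month counts per concept, walk
# consecutive months (zeros inserted inside the span), flag on >= 100% change
oracle_temporal_flagged <- function(concepts, dates, threshold = 1) {
  d <- as.Date(dates, format = "%Y-%m-%d")
  keep <- !is.na(d) & grepl("^\\d{4}-\\d{2}-\\d{2}$", dates)
  concepts <- concepts[keep]; d <- d[keep]
  mindex <- as.integer(format(d, "%Y")) * 12L + as.integer(format(d, "%m"))
  out <- character(0)
  for (cc in unique(concepts)) {
    mi <- mindex[concepts == cc]
    cnt <- integer(0)
    for (m in seq(min(mi), max(mi))) cnt <- c(cnt, sum(mi == m))
    hit <- FALSE
    if (length(cnt) >= 2L) {
      for (j in 2:length(cnt)) {
        if (cnt[j - 1] > 0 && abs(cnt[j] - cnt[j - 1]) / cnt[j - 1] >= threshold - 1e-9)
          hit <- TRUE
      }
    }
    if (hit) out <- c(out, cc)
  }
  sort(out)
}

oracle_value_range <- function(values, bound, direction = "max_le") {
  n <- 0L
  for (v in values) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) next
    if (direction == "max_le" && num > bound) n <- n + 1L
    if (direction == "min_ge" && num < bound) n <- n + 1L
  }
  n
}

oracle_count_by_person <- function(categories, persons) {
  seen <- list()
  for (i in seq_along(categories)) {
    k <- categories[[i]]
    seen[[k]] <- union(seen[[k]], persons[[i]])
  }
  sort(vapply(seen, length, 0L), decreasing = TRUE)
}

# write an ad-hoc delimited dataset from named data.frames
write_tiny <- function(tables, dir = tempfile("tiny_")) {
  dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  dir
}

# minimal two-table manifest used by small rule/profile tests
tiny_manifest <- function(tables) {
  schema_manifest(lapply(names(tables), function(nm)
    table_spec(nm, lapply(names(tables[[nm]]), column_spec))))
}

# clean base dataset shared across injection tests (short span so every
# domain concept is active in many months)
base_clean_dataset <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      cfg <- generator_config(n_persons = 120, seed = 2024,
                              date_start = "2019-01", date_end = "2019-12")
      dir <<- generate_clean(cfg, tempfile("base_clean_"))
    }
    dir
  }
})

copy_dataset <- function(src) {
  dst <- tempfile("copy_")
  dir.create(dst)
  file.copy(list.files(src, full.names = TRUE), dst)
  dst
}
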