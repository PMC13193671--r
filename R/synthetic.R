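#' @title Synthetic CDM generator and defect injection
#' @description Seeded generation of clean CDM-style datasets, an
#' exact-count defect injector producing a machine-readable truth manifest,
#' and a fixture builder that regenerates the headline numerator/denominator
#' pairs of a large hospital EHR audit at configurable scale. Realism is
#' limited to the statistical structure the assessment consumes (row
#' counts, missingness, concept mapping, monthly event counts, value
#' ranges) -- there are no disease trajectories or visit careflows.
#' @name synthetic
NULL

#' Configuration for the clean synthetic generator
#'
#' @param n_persons Number of persons (>= 1).
#' @param seed RNG seed; a fixed seed yields byte-identical datasets.
#' @param date_start,date_end Calendar months (`"YYYY-MM"`) bounding all
#'   event dates.
#' @param events_per_person Named mean event counts per domain
#'   (`visit`, `condition`, `drug`, `procedure`, `measurement`,
#'   `observation`).
#' @param dictionary Concept pools, a [concept_dictionary()].
#' @return A `generator_config`.
#' @export
generator_config <- function(n_persons = 500L, seed = 1L,
                             date_start = "2005-01", date_end = "2023-12",
                             events_per_person = c(visit = 3, condition = 4,
                                                   drug = 4, procedure = 2,
                                                   measurement = 6, observation = 3),
                             dictionary = default_dictionary()) {
  if (!is.numeric(n_persons) || n_persons < 1)
    validation_error("n_persons must be >= 1")
  m0 <- parse_month(date_start); m1 <- parse_month(date_end)
  if (m0 > m1) validation_error("date_start must not be after date_end")
  structure(list(n_persons = as.integer(n_persons), seed = as.integer(seed),
                 date_start = date_start, date_end = date_end,
                 months = seq(m0, m1),
                 events_per_person = events_per_person,
                 dictionary = dictionary),
            class = "generator_config")
}

concept_pool <- function(dictionary, domain, vocab = NULL) {
  e <- dictionary$entries[domain_id == domain & concept_id != "0"]
  if (!is.null(vocab)) e <- e[vocabulary_id %in% vocab]
  e$concept_id
}

# assign a calendar date to every row so that each concept's monthly count
# is near constant: concepts with fewer than two events per month are
# concentrated in a single month (one bucket, no transitions), all others
# spread evenly (consecutive counts differ by at most one, so the relative
# change stays far below 100%). either way the default discontinuity
# detector never fires on clean output.
spread_concept_dates <- function(concepts, months) {
  n <- length(concepts)
  mi <- integer(n)
  idx <- split(seq_len(n), concepts)
  M <- length(months)
  for (rows in idx) {
    k <- length(rows)
    if (k < 2L * M) {
      mi[rows] <- months[[sample.int(M, 1L)]]
    } else {
      per_month <- apportion(rep(1, M), k)
      mi[rows] <- rep(months, per_month)
    }
  }
  day <- sample.int(28L, n, replace = TRUE)
  sprintf("%s-%02d", month_label(mi), day)
}

empty_cols <- function(cols) {
  data.table::as.data.table(stats::setNames(rep(list(character(0)), length(cols)), cols))
}

make_emitter <- function(locator, dialect) {
  if (dialect == "delimited_directory") {
    dir.create(locator, recursive = TRUE, showWarnings = FALSE)
  } else {
    if (file.exists(locator)) unlink(locator)
    con <- DBI::dbConnect(RSQLite::SQLite(), locator)
    DBI::dbDisconnect(con)
  }
  function(name, dt) write_table_inplace(locator, dialect, name, dt)
}

#' Generate a clean synthetic CDM dataset
#'
#' All 39 manifest tables are written and populated consistently: every
#' event references an existing person, all concept ids are drawn from the
#' dictionary pools (never 0), all values are in range, every rule-targeted
#' value column is populated, and each concept's monthly event counts are
#' constant. The default rulebook therefore flags zero records on every
#' incompleteness-class rule. Output is byte-identical under a fixed seed.
#'
#' @param config A [generator_config()].
#' @param dir Target locator (directory or SQLite file path).
#' @param dialect Storage dialect.
#' @return The locator, invisibly.
#' @export
generate_clean <- function(config, dir = tempfile("cdm_clean_"),
                           dialect = "delimited_directory") {
  stopifnot(inherits(config, "generator_config"))
  dialect <- match.arg(dialect, DIALECTS)
  dict <- config$dictionary
  months <- config$months
  n <- config$n_persons
  epp <- config$events_per_person
  emit <- make_emitter(dir, dialect)
  with_seed(config$seed, {
    pid <- as.character(seq_len(n))
    person <- data.table::data.table(
      person_id = pid,
      gender_concept_id = sample(c("8507", "8532"), n, replace = TRUE),
      year_of_birth = as.character(sample(1930:2015, n, replace = TRUE)),
      race_concept_id = "38003585",
      ethnicity_concept_id = "38003564",
      gender_source_value = "G", race_source_value = "Korean",
      ethnicity_source_value = "Not Hispanic")
    emit("person", person)
    emit("observation_period", data.table::data.table(
      observation_period_id = pid, person_id = pid,
      observation_period_start_date = sprintf("%s-01", month_label(months[1])),
      observation_period_end_date = sprintf("%s-28", month_label(months[length(months)]))))

    event_table <- function(domain_total, pool) {
      E <- max(length(pool), as.integer(round(domain_total)))
      cc <- rep(pool, apportion(rep(1, length(pool)), E))
      data.table::data.table(id = as.character(seq_len(E)),
                             person_id = sample(pid, E, replace = TRUE),
                             concept_id = cc,
                             date = spread_concept_dates(cc, months))
    }

    vis <- event_table(n * epp[["visit"]], concept_pool(dict, "Visit"))
    emit("visit_occurrence", data.table::data.table(
      visit_occurrence_id = vis$id, person_id = vis$person_id,
      visit_concept_id = vis$concept_id, visit_start_date = vis$date,
      visit_end_date = vis$date, visit_source_value = "V"))
    emit("visit_detail", data.table::data.table(
      visit_detail_id = vis$id[1:max(1, nrow(vis) %/% 10)],
      person_id = vis$person_id[1:max(1, nrow(vis) %/% 10)],
      visit_detail_concept_id = vis$concept_id[1:max(1, nrow(vis) %/% 10)],
      visit_detail_start_date = vis$date[1:max(1, nrow(vis) %/% 10)]))

    cond <- event_table(n * epp[["condition"]], concept_pool(dict, "Condition"))
    emit("condition_occurrence", data.table::data.table(
      condition_occurrence_id = cond$id, person_id = cond$person_id,
      condition_concept_id = cond$concept_id, condition_start_date = cond$date,
      condition_source_value = paste0("K", cond$concept_id)))
    emit("condition_era", data.table::data.table(
      condition_era_id = cond$id, person_id = cond$person_id,
      condition_concept_id = cond$concept_id,
      condition_era_start_date = cond$date, condition_era_end_date = cond$date))

    drug <- event_table(n * epp[["drug"]], concept_pool(dict, "Drug"))
    emit("drug_exposure", data.table::data.table(
      drug_exposure_id = drug$id, person_id = drug$person_id,
      drug_concept_id = drug$concept_id, drug_exposure_start_date = drug$date,
      days_supply = as.character(sample(c(7L, 14L, 30L, 60L, 90L), nrow(drug), replace = TRUE)),
      quantity = as.character(sample(1:60, nrow(drug), replace = TRUE)),
      dose_unit_source_value = "mg",
      drug_source_value = paste0("D", drug$concept_id)))
    emit("drug_era", data.table::data.table(
      drug_era_id = drug$id, person_id = drug$person_id,
      drug_concept_id = drug$concept_id,
      drug_era_start_date = drug$date, drug_era_end_date = drug$date))
    emit("dose_era", data.table::data.table(
      dose_era_id = drug$id[1:max(1, nrow(drug) %/% 5)],
      person_id = drug$person_id[1:max(1, nrow(drug) %/% 5)],
      drug_concept_id = drug$concept_id[1:max(1, nrow(drug) %/% 5)],
      dose_value = "1"))

    proc <- event_table(n * epp[["procedure"]], concept_pool(dict, "Procedure"))
    emit("procedure_occurrence", data.table::data.table(
      procedure_occurrence_id = proc$id, person_id = proc$person_id,
      procedure_concept_id = proc$concept_id, procedure_date = proc$date,
      procedure_source_value = paste0("P", proc$concept_id)))

    meas <- event_table(n * epp[["measurement"]], concept_pool(dict, "Measurement"))
    mval <- as.character(round(stats::runif(nrow(meas), 1, 200), 1))
    emit("measurement", data.table::data.table(
      measurement_id = meas$id, person_id = meas$person_id,
      measurement_concept_id = meas$concept_id, measurement_date = meas$date,
      value_as_number = mval, unit_source_value = "mg/dL",
      value_source_value = mval))

    obs <- event_table(n * epp[["observation"]], concept_pool(dict, "Observation"))
    emit("observation", data.table::data.table(
      observation_id = obs$id, person_id = obs$person_id,
      observation_concept_id = obs$concept_id, observation_date = obs$date,
      value_as_string = sample(c("positive", "negative", "normal finding",
                                 "abnormal finding"), nrow(obs), replace = TRUE),
      observation_source_value = paste0("O", obs$concept_id)))

    n_death <- max(1L, n %/% 50L)
    dpid <- sample(pid, n_death)
    emit("death", data.table::data.table(
      person_id = dpid,
      death_date = spread_concept_dates(rep("death", n_death), months),
      cause_concept_id = sample(concept_pool(dict, "Condition"), n_death, replace = TRUE),
      cause_source_value = paste0("I", sample(10:99, n_death, replace = TRUE))))

    emit("device_exposure", data.table::data.table(
      device_exposure_id = "1", person_id = pid[1],
      device_concept_id = "45768197", device_exposure_start_date = "2019-03-07"))
    emit("note", data.table::data.table(
      note_id = "1", person_id = pid[1], note_date = "2020-01-15",
      note_text = "clinical narrative"))
    emit("note_nlp", data.table::data.table(
      note_nlp_id = "1", note_id = "1", lexical_variant = "narrative"))
    n_spec <- max(1L, n %/% 10L)
    emit("specimen", data.table::data.table(
      specimen_id = as.character(seq_len(n_spec)),
      person_id = sample(pid, n_spec, replace = TRUE),
      specimen_concept_id = "4001225",
      specimen_date = spread_concept_dates(rep("4001225", n_spec), months)))
    emit("fact_relationship", data.table::data.table(
      domain_concept_id_1 = "21", fact_id_1 = "1",
      domain_concept_id_2 = "27", fact_id_2 = "1",
      relationship_concept_id = "44818890"))
    emit("location", data.table::data.table(
      location_id = as.character(1:10),
      city = c("Incheon", "Seoul", "Busan", "Daegu", "Daejeon",
               "Gwangju", "Suwon", "Ulsan", "Changwon", "Seongnam"),
      state = rep(c("Incheon", "Seoul", "Gyeonggi", "Gyeongsang", "Chungcheong"), 2),
      zip = sprintf("%05d", 1:10), location_source_value = paste0("L", 1:10)))
    emit("care_site", data.table::data.table(
      care_site_id = as.character(1:10),
      care_site_name = sprintf("Care site %02d", 1:10),
      place_of_service_concept_id = "9202",
      place_of_service_source_value = "OP"))
    emit("provider", data.table::data.table(
      provider_id = as.character(1:10),
      provider_name = sprintf("Provider %02d", 1:10),
      specialty_concept_id = "38004446"))
    emit("payer_plan_period", data.table::data.table(
      payer_plan_period_id = "1", person_id = pid[1],
      payer_plan_period_start_date = "2010-01-01"))
    emit("cost", data.table::data.table(cost_id = "1", cost_event_id = "1",
                                        total_charge = "100"))
    emit("metadata", data.table::data.table(
      metadata_concept_id = "0", name = "generated_by",
      value_as_string = "cdmaudit synthetic generator"))
    emit("cdm_source", data.table::data.table(
      cdm_source_name = "cdmaudit synthetic CDM", cdm_version = "v5.3",
      vocabulary_version = "synthetic-2023"))

    vocabs <- sort(unique(dict$entries$vocabulary_id))
    emit("vocabulary", data.table::data.table(
      vocabulary_id = vocabs, vocabulary_name = paste(vocabs, "vocabulary"),
      vocabulary_reference = "synthetic",
      vocabulary_version = paste0(vocabs, "-2023-08")))
    cz <- dict$entries
    emit("concept", data.table::data.table(
      concept_id = cz$concept_id, concept_name = cz$concept_name,
      domain_id = cz$domain_id, vocabulary_id = cz$vocabulary_id,
      concept_class_id = "Clinical Finding", standard_concept = "S",
      concept_code = paste0("C", cz$concept_id), invalid_reason = NA_character_))
    emit("domain", data.table::data.table(
      domain_id = sort(unique(cz$domain_id)),
      domain_name = sort(unique(cz$domain_id)),
      domain_concept_id = as.character(seq_along(unique(cz$domain_id)))))
    emit("concept_class", data.table::data.table(
      concept_class_id = c("Clinical Finding", "Procedure", "Drug Product"),
      concept_class_name = c("Clinical Finding", "Procedure", "Drug Product")))
    cr_n <- min(200L, nrow(cz)^2)
    emit("concept_relationship", data.table::data.table(
      concept_id_1 = sample(cz$concept_id, cr_n, replace = TRUE),
      concept_id_2 = sample(cz$concept_id, cr_n, replace = TRUE),
      relationship_id = "Maps to", valid_start_date = "1970-01-01",
      valid_end_date = "2099-12-31", invalid_reason = NA_character_))
    emit("relationship", data.table::data.table(
      relationship_id = c("Maps to", "Mapped from", "Is a"),
      relationship_name = c("Maps to", "Mapped from", "Is a")))
    emit("concept_synonym", data.table::data.table(
      concept_id = cz$concept_id, concept_synonym_name = tolower(cz$concept_name)))
    emit("concept_ancestor", data.table::data.table(
      ancestor_concept_id = cz$concept_id, descendant_concept_id = cz$concept_id))
    emit("source_to_concept_map", data.table::data.table(
      source_code = paste0("S", cz$concept_id), source_concept_id = "0",
      target_concept_id = cz$concept_id))
    dr <- concept_pool(dict, "Drug")
    emit("drug_strength", data.table::data.table(
      drug_concept_id = dr, ingredient_concept_id = dr,
      amount_value = "100", invalid_reason = NA_character_))
    emit("cohort", data.table::data.table(
      cohort_definition_id = "1", subject_id = pid[1], cohort_start_date = "2015-06-01"))
    emit("cohort_definition", data.table::data.table(
      cohort_definition_id = "1", cohort_definition_name = "all persons"))
    emit("attribute_definition", data.table::data.table(
      attribute_definition_id = "1", attribute_name = "age at entry"))
    emit("cohort_attribute", data.table::data.table(
      cohort_definition_id = "1", subject_id = pid[1],
      attribute_definition_id = "1", value_as_number = "42"))
  })
  invisible(dir)
}

DEFECT_KINDS <- c("missing_value", "special_value", "unmapped_concept",
                  "temporal_gap", "out_of_range", "empty_table", "drop_table")

#' Declare one data defect to plant
#'
#' @param kind One of `missing_value`, `special_value`, `unmapped_concept`,
#'   `temporal_gap`, `out_of_range`, `empty_table`, `drop_table`.
#' @param table Target table.
#' @param column Target column (value or concept column); `date_column` for
#'   `temporal_gap` goes in `params`.
#' @param exact_count Exact number of records to mutate (row-level kinds).
#' @param rate Alternative to `exact_count`: fraction of the table's rows.
#' @param params Kind-specific: `value` (special/out-of-range replacement),
#'   `concept_id` + `date_column` + `gap_months` for `temporal_gap`,
#'   `allow_overlap` to let two specs hit the same rows.
#' @return A `defect_spec`.
#' @export
defect_spec <- function(kind, table, column = NULL, exact_count = NULL,
                        rate = NULL, params = list()) {
  if (!kind %in% DEFECT_KINDS)
    validation_error(sprintf("unknown defect kind '%s'", kind))
  row_level <- kind %in% c("missing_value", "special_value", "unmapped_concept", "out_of_range")
  if (row_level) {
    if (is.null(column)) validation_error(sprintf("%s requires a column", kind))
    if (is.null(exact_count) == is.null(rate))
      validation_error(sprintf("%s requires exactly one of exact_count or rate", kind))
  }
  if (kind == "temporal_gap" && is.null(params$date_column))
    validation_error("temporal_gap requires params$date_column")
  structure(list(kind = kind, table = tolower(table),
                 column = if (is.null(column)) NULL else tolower(column),
                 exact_count = if (is.null(exact_count)) NULL else as.integer(exact_count),
                 rate = rate, params = params),
            class = "defect_spec")
}

#' Assemble a seeded defect plan
#' @param specs List of [defect_spec()]s, applied in order.
#' @param seed RNG seed governing all row sampling.
#' @return A `defect_plan`.
#' @export
defect_plan <- function(specs, seed = 1L) {
  specs <- lapply(specs, function(s) {
    if (inherits(s, "defect_spec")) s else do.call(defect_spec, s)
  })
  structure(list(specs = specs, seed = as.integer(seed)), class = "defect_plan")
}

#' Plant defects into a dataset, in place
#'
#' Applies each [defect_spec()] in order and returns a truth manifest
#' recording, per spec, exactly which records were altered. Row-level specs
#' sample rows without replacement; two specs targeting the same column
#' never reuse a row unless `params$allow_overlap = TRUE`. A spec whose
#' `exact_count` exceeds the eligible records aborts the whole plan before
#' any mutation reaches the dataset.
#'
#' @param locator Dataset locator (directory or SQLite file).
#' @param plan A [defect_plan()].
#' @param dialect Storage dialect; inferred from the locator when omitted.
#' @return A `defect_truth` list: `seed` and one record per spec with
#'   `kind`, `table`, `column`, `requested`, `realized`, `row_ids` (indices
#'   into the pre-mutation table) and kind-specific fields (gap months,
#'   planted value).
#' @export
apply_defects <- function(locator, plan, dialect = NULL) {
  stopifnot(inherits(plan, "defect_plan"))
  if (is.null(dialect)) dialect <- if (dir.exists(locator)) "delimited_directory" else "sql_database"
  h <- open_dataset(locator, dialect)
  on.exit(close_dataset(h), add = TRUE)
  tables <- new.env(parent = emptyenv())
  get_tab <- function(nm) {
    if (!exists(nm, envir = tables, inherits = FALSE)) {
      if (!table_exists(h, nm)) not_available_error(nm)
      h$cache_name <- NULL  # never serve stale cache across specs
      assign(nm, data.table::copy(read_table_raw(h, nm)), envir = tables)
    }
    get(nm, envir = tables, inherits = FALSE)
  }
  used <- new.env(parent = emptyenv())
  used_get <- function(key) if (exists(key, envir = used, inherits = FALSE))
    get(key, envir = used, inherits = FALSE) else integer(0)
  dropped <- character(0)
  truth <- vector("list", length(plan$specs))

  with_seed(plan$seed, {
    for (i in seq_along(plan$specs)) {
      sp <- plan$specs[[i]]
      rec <- list(kind = sp$kind, table = sp$table, column = sp$column)
      if (sp$kind == "drop_table") {
        dropped <- union(dropped, sp$table)
        if (exists(sp$table, envir = tables, inherits = FALSE))
          rm(list = sp$table, envir = tables)
        rec$realized <- NA_integer_
      } else if (sp$kind == "empty_table") {
        dt <- get_tab(sp$table)
        assign(sp$table, dt[0L], envir = tables)
        rec$realized <- 0L
      } else if (sp$kind == "temporal_gap") {
        dt <- get_tab(sp$table)
        dcol <- tolower(sp$params$date_column)
        ccol <- sp$column %||% tolower(sp$params$concept_column %||%
          validation_error("temporal_gap requires a concept column"))
        k <- as.integer(sp$params$gap_months %||% 3L)
        d <- parse_iso_date(dt[[dcol]])
        mi <- month_index(d)
        cid <- sp$params$concept_id %||% {
          # default target: the concept active in the most calendar months
          span <- data.table::data.table(concept = dt[[ccol]], m = mi)[!is.na(m),
            list(n = data.table::uniqueN(m)), by = concept]
          span$concept[which.max(span$n)]
        }
        mo <- sort(unique(mi[dt[[ccol]] == cid & !is.na(mi)]))
        if (length(mo) < k + 2L)
          validation_error(sprintf(
            "temporal_gap: concept %s spans only %d active months; need >= %d",
            cid, length(mo), k + 2L))
        start_pos <- max(2L, (length(mo) - k) %/% 2L + 1L)
        gap <- mo[start_pos:(start_pos + k - 1L)]
        drop_rows <- which(dt[[ccol]] == cid & mi %in% gap)
        assign(sp$table, dt[-drop_rows], envir = tables)
        rec$concept_id <- as.character(cid)
        rec$gap_months <- month_label(gap)
        rec$realized <- length(drop_rows)
        rec$row_ids <- drop_rows
      } else {
        dt <- get_tab(sp$table)
        col <- sp$column
        if (!col %in% names(dt)) dt[, (col) := NA_character_]
        eligible <- switch(sp$kind,
          missing_value = which(!is.na(dt[[col]])),
          special_value = which(!flag_missing_special(dt[[col]])),
          unmapped_concept = which(!is_unmapped_concept(dt[[col]])),
          out_of_range = {
            v <- suppressWarnings(as.numeric(dt[[col]]))
            which(!is.na(v))
          })
        key <- paste0(sp$table, "|", col)
        if (!isTRUE(sp$params$allow_overlap))
          eligible <- setdiff(eligible, used_get(key))
        k <- sp$exact_count %||% scale_count(nrow(dt), sp$rate)
        if (k > length(eligible))
          validation_error(sprintf(
            "defect plan infeasible: spec %d (%s on %s.%s) wants %d of %d eligible records",
            i, sp$kind, sp$table, col, k, length(eligible)))
        rows <- sort(sample_rows(eligible, k))
        assign(key, c(used_get(key), rows), envir = used)
        newval <- switch(sp$kind,
          missing_value = NA_character_,
          special_value = as.character(sp$params$value %||% "*"),
          unmapped_concept = "0",
          out_of_range = as.character(sp$params$value %||% 9999))
        if (k > 0L) data.table::set(dt, i = rows, j = col, value = newval)
        assign(sp$table, dt, envir = tables)
        rec$requested <- k
        rec$realized <- k
        rec$row_ids <- rows
        if (sp$kind %in% c("special_value", "out_of_range")) rec$value <- newval
      }
      truth[[i]] <- rec
    }
  })
  # all specs validated and applied in memory; now persist
  for (nm in ls(tables))
    write_table_inplace(locator, dialect, nm, get(nm, envir = tables, inherits = FALSE))
  for (nm in dropped) drop_table_inplace(locator, dialect, nm)
  structure(list(seed = plan$seed, specs = truth), class = "defect_truth")
}
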