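test_that("missing/special flagging matches a record-by-record oracle", {
  vals <- c("", "-", "*", "A1", "  ", "NULL", "n/a", "ok value", "./-", "x*")
  d <- write_tiny(list(vocabulary = data.frame(vocabulary_id = as.character(1:10),
                                               vocabulary_version = vals,
                                               stringsAsFactors = FALSE)))
  h <- open_dataset(d)
  r <- run_missing_special(h, "vocabulary", "vocabulary_version")
  expect_identical(r$total, 10)
  expect_identical(r$flagged, as.numeric(oracle_missing_special(vals)))
  expect_identical(r$flagged, 7)  # "", "-", "*", "  ", NULL, n/a, ./-
  expect_equal(r$proportion_pct, 70.0)
  expect_identical(r$interpretation, "deficit")

  # clean column flags nothing; custom sentinel set is honored
  r0 <- run_missing_special(h, "vocabulary", "vocabulary_id")
  expect_identical(r0$flagged, 0)
  expect_equal(r0$proportion_pct, 0.0)
  rs <- run_missing_special(h, "vocabulary", "vocabulary_version",
                            special_values = c("ok value"), special_chars = character(0))
  expect_identical(rs$flagged, as.numeric(oracle_missing_special(
    vals, sentinels = "ok value", chars = character(0))))

  # absent column: strongest incompleteness, all rows flagged with warning
  expect_warning(ra <- run_missing_special(h, "vocabulary", "not_a_column"),
                 "column-absent")
  expect_identical(ra$flagged, 10)

  # not-available table is a result, not an exception
  rna <- run_missing_special(h, "note", "note_text")
  expect_identical(rna$interpretation, "not_applicable")
})

test_that("unmapped-concept counting works in rows and persons units", {
  drug <- data.frame(
    person_id = c("a", "a", "b", "c", "d", "e", "f", "f"),
    drug_concept_id = c("11", "0", "12", "0", "13", "14", "15", "16"),
    stringsAsFactors = FALSE)
  d <- write_tiny(list(drug_exposure = drug))
  h <- open_dataset(d)

  rr <- run_unmapped(h, "drug_exposure", "drug_concept_id", unit = "rows")
  expect_identical(rr$flagged, as.numeric(oracle_unmapped_rows(drug$drug_concept_id)))
  expect_identical(rr$flagged, 2)

  rp <- run_unmapped(h, "drug_exposure", "drug_concept_id", unit = "persons")
  ora <- oracle_unmapped_persons(drug$drug_concept_id, drug$person_id)
  expect_identical(rp$flagged, as.numeric(ora[["flagged"]]))
  expect_identical(rp$total, as.numeric(ora[["total"]]))
  expect_identical(c(rp$flagged, rp$total), c(2, 6))  # persons a and c of 6

  # fully unmapped column -> 100%
  person <- data.frame(person_id = as.character(1:5),
                       ethnicity_concept_id = rep("0", 5), stringsAsFactors = FALSE)
  h2 <- open_dataset(write_tiny(list(person = person)))
  r100 <- run_unmapped(h2, "person", "ethnicity_concept_id")
  expect_equal(r100$proportion_pct, 100.0)
})

make_series_dataset <- function(counts_by_concept, start = "2021-01") {
  # counts_by_concept: named list of monthly count vectors (0 = gap month)
  rows <- list()
  m0 <- as.integer(substr(start, 1, 4)) * 12L + as.integer(substr(start, 6, 7)) - 1L
  for (cc in names(counts_by_concept)) {
    cnt <- counts_by_concept[[cc]]
    for (j in seq_along(cnt)) {
      if (cnt[j] == 0) next
      mi <- m0 + j - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        person_id = "p", condition_concept_id = cc,
        condition_start_date = sprintf("%04d-%02d-%02d", mi %/% 12L, mi %% 12L + 1L,
                                       seq_len(cnt[j])),
        stringsAsFactors = FALSE)
    }
  }
  write_tiny(list(condition_occurrence = do.call(rbind, rows)))
}

test_that("temporal discontinuity flags 100% month-to-month changes and only those", {
  d <- make_series_dataset(list(steady = c(5, 5, 5), gap = c(5, 0, 3), doubling = c(4, 8),
                                rising = c(10, 14, 19)))
  h <- open_dataset(d)
  r <- run_temporal_discontinuity(h, "condition_occurrence", "condition_concept_id",
                                  "condition_start_date")
  expect_identical(r$total, 4)
  expect_setequal(r$detail$flagged_concepts$concept_id, c("gap", "doubling"))
  # drop to zero is a 100% change: flagged at the second month
  g <- r$detail$flagged_concepts[concept_id == "gap"]
  expect_identical(g$month_from, "2021-01")
  expect_identical(g$month_to, "2021-02")
  expect_identical(c(g$count_from, g$count_to), c(5L, 0L))
  # |8-4|/4 = 1.0 meets the threshold
  expect_true("doubling" %in% r$detail$flagged_concepts$concept_id)
  # steady and sub-threshold series never flag
  expect_false(any(c("steady", "rising") %in% r$detail$flagged_concepts$concept_id))
})

test_that("temporal detector matches the oracle, ignores record order, and obeys the month switch", {
  set.seed(31)
  series <- list()
  for (i in 1:20) {
    base <- sample(2:9, 1)
    cnt <- rep(base, 6)
    if (i %% 2 == 0) cnt[sample(2:5, 1)] <- 0  # interior zero gap
    series[[sprintf("c%02d", i)]] <- cnt
  }
  d <- make_series_dataset(series)
  h <- open_dataset(d)
  r <- run_temporal_discontinuity(h, "condition_occurrence", "condition_concept_id",
                                  "condition_start_date")
  tab <- read_table(h, "condition_occurrence")
  expect_identical(sort(r$detail$flagged_concepts$concept_id),
                   oracle_temporal_flagged(tab$condition_concept_id,
                                           tab$condition_start_date))
  # every gapped series flags; every constant series does not
  gapped <- names(series)[vapply(series, function(x) any(x == 0), TRUE)]
  expect_setequal(r$detail$flagged_concepts$concept_id, gapped)

  # shuffling record order changes nothing
  shuf <- tab[sample(nrow(tab))]
  h2 <- open_dataset(write_tiny(list(condition_occurrence = as.data.frame(shuf))))
  r2 <- run_temporal_discontinuity(h2, "condition_occurrence", "condition_concept_id",
                                   "condition_start_date")
  expect_identical(r2$detail$flagged_concepts, r$detail$flagged_concepts)

  # observed-months-only mode skips the inserted zero months: a series with
  # counts 5, <18-month silence>, 4 is a 20% observed change, not a gap
  d3 <- make_series_dataset(list(sparse = c(5, rep(0, 18), 4)))
  h3 <- open_dataset(d3)
  expect_identical(run_temporal_discontinuity(h3, "condition_occurrence",
    "condition_concept_id", "condition_start_date", insert_zero_months = FALSE)$flagged, 0)
  expect_identical(run_temporal_discontinuity(h3, "condition_occurrence",
    "condition_concept_id", "condition_start_date")$flagged, 1)

  # onset (zero -> positive) is reported but never flagged
  d4 <- make_series_dataset(list(onset = c(2, 0, 0, 2)))
  r4 <- run_temporal_discontinuity(open_dataset(d4), "condition_occurrence",
                                   "condition_concept_id", "condition_start_date")
  expect_identical(r4$flagged, 1)  # the drop flags; the onset itself does not add
  expect_true(r4$detail$n_onsets >= 1)

  # a wholly unparseable date column is not applicable
  bad <- data.frame(person_id = "p", condition_concept_id = "c",
                    condition_start_date = c("unknown", "12/31/2020"),
                    stringsAsFactors = FALSE)
  r5 <- run_temporal_discontinuity(open_dataset(write_tiny(list(condition_occurrence = bad))),
                                   "condition_occurrence", "condition_concept_id",
                                   "condition_start_date")
  expect_identical(r5$interpretation, "not_applicable")
})

test_that("value-range bounds are strict and report per-concept extremes", {
  drug <- data.frame(
    person_id = as.character(1:6),
    drug_concept_id = c("1", "1", "2", "2", "3", "3"),
    days_supply = c("30", "90", "181", "x", "180", "200"),
    quantity = c("601", "650", "600", "1", "2", "3"),
    stringsAsFactors = FALSE)
  h <- open_dataset(write_tiny(list(drug_exposure = drug)))

  r <- run_value_range(h, "drug_exposure", "days_supply", bound = 180,
                       group_column = "drug_concept_id")
  expect_identical(r$flagged, as.numeric(oracle_value_range(drug$days_supply, 180)))
  expect_identical(r$flagged, 2)            # 181 and 200; 180 passes, "x" skipped
  expect_identical(r$detail$n_nonnumeric, 1L)
  expect_identical(r$detail$per_concept$extreme[r$detail$per_concept$concept_id == "3"], 200)

  rq <- run_value_range(h, "drug_exposure", "quantity", bound = 600,
                        group_column = "drug_concept_id")
  expect_identical(rq$flagged, 2)           # 601, 650; 600 passes
  expect_identical(rq$detail$per_concept$extreme, 650)

  rmin <- run_value_range(h, "drug_exposure", "quantity", bound = 2, direction = "min_ge")
  expect_identical(rmin$flagged, as.numeric(oracle_value_range(drug$quantity, 2, "min_ge")))
})

test_that("rulebooks load, validate, and run in declared order", {
  rb <- default_rulebook()
  ids <- vapply(rb, `[[`, "", "id")
  expect_true("vocabulary.vocabulary_version.missing" %in% ids)
  expect_identical(sum(vapply(rb, function(r) r$semantic_class == "expected_null", TRUE)), 2L)
  expect_setequal(unique(vapply(rb, `[[`, "", "kind")),
                  c("missing_or_special", "unmapped_concept",
                    "temporal_discontinuity", "value_range"))

  f <- tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  - {id: one, kind: missing_or_special, table: t, column: c}"), f)
  expect_length(load_rulebook(f), 1)
  writeLines(c("rules:",
               "  - {id: bad, kind: value_range, table: t, column: c}"), f)
  expect_error(load_rulebook(f), "bound", class = "cdm_validation_error")
  expect_error(rule_spec("x", "no_such_kind", "t", "c"), "unknown kind")

  # empty rulebook -> empty results; rules on missing tables -> not_applicable
  d <- write_tiny(list(person = data.frame(person_id = "1", race_concept_id = "5",
                                           ethnicity_concept_id = "5",
                                           stringsAsFactors = FALSE)))
  h <- open_dataset(d)
  expect_length(run_rulebook(h, structure(list(), class = "rulebook")), 0)
  res <- run_rulebook(h)
  expect_identical(vapply(res, `[[`, "", "rule_id"),
                   vapply(default_rulebook(), `[[`, "", "id"))
  expect_identical(res[[1]]$interpretation, "not_applicable")  # no vocabulary table
})

test_that("semantic class changes interpretation but never the counts", {
  vals <- c(NA, NA, NA, "D")
  d <- write_tiny(list(concept_relationship = data.frame(
    concept_id_1 = as.character(1:4), invalid_reason = vals, stringsAsFactors = FALSE)))
  h <- open_dataset(d)
  inc <- run_missing_special(h, "concept_relationship", "invalid_reason",
                             semantic_class = "incompleteness")
  exp <- run_missing_special(h, "concept_relationship", "invalid_reason",
                             semantic_class = "expected_null")
  expect_identical(inc$flagged, exp$flagged)
  expect_identical(inc$total, exp$total)
  expect_identical(inc$interpretation, "deficit")
  expect_identical(exp$interpretation, "valid_by_default")
})
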