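test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_persons = 60, seed = 7,
                          date_start = "2020-01", date_end = "2021-12")
  d1 <- generate_clean(cfg, tempfile("s1_"))
  d2 <- generate_clean(cfg, tempfile("s2_"))
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)), info = f)
  # different seed: same schema and sizes fixed by config, different content
  d3 <- generate_clean(generator_config(n_persons = 60, seed = 8,
                                        date_start = "2020-01", date_end = "2021-12"),
                       tempfile("s3_"))
  expect_identical(sort(list.files(d3)), f1)
  h1 <- open_dataset(d1); h3 <- open_dataset(d3)
  expect_identical(row_count(h1, "person"), row_count(h3, "person"))
  expect_false(identical(readLines(file.path(d1, "person.csv")),
                         readLines(file.path(d3, "person.csv"))))
})

test_that("a clean dataset is structurally complete and passes every incompleteness rule", {
  h <- open_dataset(base_clean_dataset())
  s <- structural_report(h)
  expect_identical(s$n_empty, 0L)
  expect_identical(s$n_not_available, 0L)
  df <- as.data.frame(run_rulebook(h))
  inc <- df[df$semantic_class == "incompleteness", ]
  expect_true(all(inc$flagged == 0))
  expect_error(generator_config(n_persons = 0), "n_persons")
  expect_error(generator_config(date_start = "2023-01", date_end = "2020-01"), "date_start")
})

test_that("defect injection mutates exactly the planted records and composes without overlap", {
  d <- copy_dataset(base_clean_dataset())
  plan <- defect_plan(list(
    defect_spec("missing_value", "vocabulary", "vocabulary_version", exact_count = 4),
    defect_spec("special_value", "vocabulary", "vocabulary_version", exact_count = 3,
                params = list(value = "-")),
    defect_spec("unmapped_concept", "condition_occurrence", "condition_concept_id",
                exact_count = 9),
    defect_spec("out_of_range", "drug_exposure", "days_supply", exact_count = 5,
                params = list(value = 365))), seed = 99)
  truth <- apply_defects(d, plan)
  expect_identical(vapply(truth$specs, `[[`, 0L, "realized"), c(4L, 3L, 9L, 5L))
  # two specs on the same column sampled disjoint rows
  expect_length(intersect(truth$specs[[1]]$row_ids, truth$specs[[2]]$row_ids), 0)

  h <- open_dataset(d)
  expect_identical(run_missing_special(h, "vocabulary", "vocabulary_version")$flagged, 7)
  expect_identical(run_unmapped(h, "condition_occurrence", "condition_concept_id",
                                unit = "rows")$flagged, 9)
  expect_identical(run_value_range(h, "drug_exposure", "days_supply", bound = 180)$flagged, 5)
})

test_that("an infeasible plan aborts before any mutation reaches the dataset", {
  d <- copy_dataset(base_clean_dataset())
  before <- tools::md5sum(list.files(d, full.names = TRUE))
  plan <- defect_plan(list(
    defect_spec("missing_value", "vocabulary", "vocabulary_version", exact_count = 2),
    defect_spec("missing_value", "vocabulary", "vocabulary_version",
                exact_count = 10000L)), seed = 1)
  expect_error(apply_defects(d, plan), "infeasible", class = "cdm_validation_error")
  expect_identical(tools::md5sum(list.files(d, full.names = TRUE)), before)
})

test_that("table-level defects and temporal gaps are recovered by the assessors", {
  d <- copy_dataset(base_clean_dataset())
  truth <- apply_defects(d, defect_plan(list(
    defect_spec("temporal_gap", "drug_exposure", "drug_concept_id",
                params = list(date_column = "drug_exposure_start_date", gap_months = 2)),
    defect_spec("empty_table", "metadata"),
    defect_spec("drop_table", "note")), seed = 5))
  h <- open_dataset(d)
  expect_identical(classify_table(h, "metadata"), "empty")
  expect_identical(classify_table(h, "note"), "not_available")
  r <- run_temporal_discontinuity(h, "drug_exposure", "drug_concept_id",
                                  "drug_exposure_start_date")
  gap_spec <- truth$specs[[1]]
  expect_true(gap_spec$concept_id %in% r$detail$flagged_concepts$concept_id)
  expect_length(gap_spec$gap_months, 2)
  expect_true(gap_spec$realized > 0)
})

test_that("rate-based magnitudes resolve against the table size", {
  d <- copy_dataset(base_clean_dataset())
  h0 <- open_dataset(d)
  n <- row_count(h0, "observation")
  truth <- apply_defects(d, defect_plan(list(
    defect_spec("missing_value", "observation", "value_as_string", rate = 0.25)), seed = 3))
  expect_identical(truth$specs[[1]]$realized, as.integer(round(0.25 * n)))
})

test_that("the reference fixture scales cohort counts by largest remainder and keeps reference tables fixed", {
  fx <- build_paper_fixture(tempfile("fxs_"), scale = 0.001, seed = 17)
  tr <- fx$truth
  for (nm in names(tr$counts)) {
    ct <- tr$counts[[nm]]
    if (ct$scaling == "cohort") {
      expect_lte(abs(ct$count - max(1, ct$base * 0.001)), 1)
    } else if (ct$scaling == "reference") {
      expect_identical(ct$count, ct$base)
    } else if (ct$scaling == "big_table") {
      expect_lte(abs(ct$count - max(1, ct$base * 0.001 / 1000)), 1)
    }
  }
  # realized tables agree with the truth manifest
  h <- open_dataset(fx$locator)
  expect_identical(row_count(h, "vocabulary"), 124L)
  expect_identical(as.numeric(row_count(h, "person")), tr$counts$persons$count)
  expect_identical(as.numeric(row_count(h, "death")), tr$counts$death_rows$count)
  # internal consistency: structural classification is scale-invariant
  s <- structural_report(h)
  expect_identical(s$n_empty, 7L)
  expect_identical(s$n_not_available, 5L)
  expect_error(build_paper_fixture(scale = 0), "scale")
})
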