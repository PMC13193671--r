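tiny_dict <- function() {
  concept_dictionary(data.frame(
    concept_id = c("8507", "8532", "9202", "9203", "c1", "c2", "v1", "v2", "v3"),
    concept_name = c("MALE", "FEMALE", "Outpatient visit", "Emergency room visit",
                     "Concept one", "Concept two", "V1 thing", "V2 thing", "V3 thing"),
    vocabulary_id = c("Gender", "Gender", "Visit", "Visit", "SNOMED", "SNOMED",
                      "LOINC", "SNOMED", "RxNorm"),
    domain_id = "x", stringsAsFactors = FALSE))
}

test_that("demographic profiles count persons and resolve concept labels", {
  person <- data.frame(
    person_id = as.character(1:8),
    gender_concept_id = c(rep("8507", 3), rep("8532", 5)),
    race_concept_id = c(rep("0", 2), rep("unknown_id", 6)),
    ethnicity_concept_id = rep("0", 8), stringsAsFactors = FALSE)
  h <- open_dataset(write_tiny(list(person = person)))
  prof <- demographic_profile(h, tiny_dict())
  expect_named(prof, c("sex", "race", "ethnicity"))

  sex <- prof$sex$entries
  expect_identical(sex$category, c("FEMALE", "MALE"))  # descending count
  expect_identical(sex$count, c(5L, 3L))
  expect_equal(sex$percent, c(62.5, 37.5))
  expect_identical(prof$sex$denominator, 8L)

  expect_identical(prof$ethnicity$entries$category, "No matching concept")
  expect_equal(prof$ethnicity$entries$percent, 100)
  # unknown non-zero ids render as concept:<id>, never fail
  expect_true("concept:unknown_id" %in% prof$race$entries$category)
})

test_that("vocabulary distributions count rows, bucket small vocabularies, keep unmapped", {
  obs <- data.frame(person_id = "p",
                    observation_concept_id = c(rep("v1", 5), rep("v2", 3), rep("v3", 2)),
                    stringsAsFactors = FALSE)
  h <- open_dataset(write_tiny(list(observation = obs)))
  vd <- vocabulary_distribution(h, "observation", "observation_concept_id", tiny_dict())
  expect_identical(vd$unit, "rows")
  expect_identical(vd$entries$category, c("LOINC", "SNOMED", "RxNorm"))
  expect_identical(vd$entries$count, c(5L, 3L, 2L))
  expect_equal(vd$entries$percent, c(50.0, 30.0, 20.0))

  # single-vocabulary table -> one entry at 100%
  one <- data.frame(person_id = "p", observation_concept_id = rep("v1", 4),
                    stringsAsFactors = FALSE)
  v1 <- vocabulary_distribution(open_dataset(write_tiny(list(observation = one))),
                                "observation", "observation_concept_id", tiny_dict())
  expect_equal(v1$entries$percent, 100)

  # sub-threshold vocabularies collapse into Other; unmapped never dropped
  big <- data.frame(person_id = "p",
                    observation_concept_id = c(rep("v1", 996), rep("v3", 2),
                                               "0", "not_in_dict"),
                    stringsAsFactors = FALSE)
  vb <- vocabulary_distribution(open_dataset(write_tiny(list(observation = big))),
                                "observation", "observation_concept_id", tiny_dict())
  expect_true("Other" %in% vb$entries$category)        # RxNorm 0.2% collapsed
  expect_false("RxNorm" %in% vb$entries$category)
  expect_identical(vb$entries$count[vb$entries$category == "Unmapped/Unknown"], 2L)
  expect_identical(sum(vb$entries$count), 1000L)
})

test_that("visit types are multi-membership over persons", {
  person <- data.frame(person_id = c("A", "B", "C", "D"),
                       gender_concept_id = "8507", race_concept_id = "8507",
                       ethnicity_concept_id = "8507", stringsAsFactors = FALSE)
  visits <- data.frame(
    person_id = c("A", "A", "A", "B", "C"),
    visit_concept_id = c("9202", "9202", "9203", "9202", "9202"),
    stringsAsFactors = FALSE)
  h <- open_dataset(write_tiny(list(person = person, visit_occurrence = visits)))
  vt <- visit_type_profile(h, tiny_dict())
  expect_true(vt$multi_membership)
  ent <- vt$entries
  # A counts once under each of outpatient and ER despite two outpatient rows
  expect_identical(ent$count[ent$category == "Outpatient visit"], 3L)
  expect_identical(ent$count[ent$category == "Emergency room visit"], 1L)
  expect_equal(ent$percent[ent$category == "Outpatient visit"], 75.0)
  expect_identical(vt$denominator, 4L)
  oracle <- oracle_count_by_person(visits$visit_concept_id, visits$person_id)
  expect_identical(sort(ent$count, decreasing = TRUE), unname(oracle))
})

test_that("top concepts rank by distinct persons with deterministic ties", {
  person <- data.frame(person_id = c("p1", "p2", "p3"),
                       gender_concept_id = "8507", race_concept_id = "8507",
                       ethnicity_concept_id = "8507", stringsAsFactors = FALSE)
  cond <- data.frame(
    person_id = c("p1", "p1", "p2", "p3", "p3"),
    condition_concept_id = c("c1", "c1", "c1", "c2", "c2"),  # dup rows for p1/c1, p3/c2
    stringsAsFactors = FALSE)
  h <- open_dataset(write_tiny(list(person = person, condition_occurrence = cond)))
  tc <- top_concepts_by_person(h, "condition_occurrence", "condition_concept_id",
                               tiny_dict(), n = 10)
  expect_identical(tc$entries$concept_id, c("c1", "c2"))  # 2 persons beats 1
  expect_identical(tc$entries$count, c(2L, 1L))           # duplicates never double-count
  expect_equal(tc$entries$percent[1], 66.7)
  expect_identical(tc$entries$category[1], "Concept one")

  # n larger than distinct concepts returns everything; ties break by id ascending
  cond2 <- data.frame(person_id = c("p1", "p2"), condition_concept_id = c("7", "3"),
                      stringsAsFactors = FALSE)
  h2 <- open_dataset(write_tiny(list(person = person, condition_occurrence = cond2)))
  tc2 <- top_concepts_by_person(h2, "condition_occurrence", "condition_concept_id",
                                tiny_dict(), n = 99)
  expect_identical(tc2$entries$concept_id, c("3", "7"))
})

test_that("profiles are invariant to record order", {
  set.seed(77)
  cond <- data.frame(
    person_id = sample(sprintf("p%02d", 1:30), 200, replace = TRUE),
    condition_concept_id = sample(c("c1", "c2", "v1"), 200, replace = TRUE),
    stringsAsFactors = FALSE)
  person <- data.frame(person_id = sprintf("p%02d", 1:30),
                       gender_concept_id = "8507", race_concept_id = "8507",
                       ethnicity_concept_id = "8507", stringsAsFactors = FALSE)
  h1 <- open_dataset(write_tiny(list(person = person, condition_occurrence = cond)))
  h2 <- open_dataset(write_tiny(list(person = person,
                                     condition_occurrence = cond[sample(nrow(cond)), ])))
  t1 <- top_concepts_by_person(h1, "condition_occurrence", "condition_concept_id", tiny_dict())
  t2 <- top_concepts_by_person(h2, "condition_occurrence", "condition_concept_id", tiny_dict())
  expect_identical(t1$entries, t2$entries)
  v1 <- vocabulary_distribution(h1, "condition_occurrence", "condition_concept_id", tiny_dict())
  v2 <- vocabulary_distribution(h2, "condition_occurrence", "condition_concept_id", tiny_dict())
  expect_identical(v1$entries, v2$entries)
})
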