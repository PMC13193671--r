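# cdmaudit

Practical completeness auditing for clinical databases laid out like the
OMOP Common Data Model (CDM).

## The problem

Hospital EHR extracts standardized into a CDM are reused for research and
model development, but "is this database complete enough for my study?" is
rarely answerable from a single metric. Completeness failures appear at
three different levels:

1. **Structure** — whole tables can be absent (never implemented in the
   ETL) or present but empty (derivation scripts never ran). An absent
   `note` table means no clinical narratives were captured at all.
2. **Values** — columns carry `NULL`s or special-character placeholders
   (`*`, `-`, `?`, `N/A`, ...), concept-id columns hold `0` ("No matching
   concept", the unmapped sentinel), event series break off for months at
   a time, and numeric fields exceed clinically plausible bounds.
3. **Coverage** — even a fully populated database may under-represent the
   populations or care settings a study needs (few intensive-care
   patients, one dominant race category, a US-centric ethnicity field that
   is structurally empty outside the US).

`cdmaudit` operationalizes this as a three-component audit:

* **Structural assessment** — every expected table is classified
  `available` / `empty` / `not_available` against a declarative schema
  manifest (the bundled default covers the 39 tables of CDM v5.3), with
  row counts, storage volume, and interpretation notes
  (`derived-table-not-populated`, `free-text-capture-gap`).
* **Rule engine** — a declarative rulebook of four check kinds:
  * `missing_or_special`: a record is flagged when its value is missing
    or, after trimming, empty, a sentinel string (`NULL`, `NA`, `N/A`,
    `UNKNOWN`), or composed solely of special characters
    (`* - . ? # / \ + , _`). Reported as flagged/total with a one-decimal
    percentage.
  * `unmapped_concept`: concept id missing or `0`; counted in rows or in
    distinct persons.
  * `temporal_discontinuity`: events bucketed by concept x calendar month;
    a concept is flagged when some month-to-month relative change
    `|c_t - c_(t-1)| / c_(t-1)` reaches the threshold (default 1.0, i.e. a
    100 % change; a drop to zero always qualifies, an onset from zero
    never does).
  * `value_range`: strict bound violations (`days_supply > 180`,
    `quantity > 600` in the default rulebook), with per-concept extremes.

  Every result carries a semantic class: `invalid_reason`-style columns
  are `NULL` by default, so their 100 % "missingness" is reported as
  `valid_by_default`, never as a deficit — detection without
  interpretation is not an assessment.
* **Profiling** — person-level distributions of sex, race and ethnicity,
  multi-membership visit-type coverage, top concepts by distinct-person
  count, and row-level mapped-vocabulary distributions (SNOMED CT, LOINC,
  RxNorm, ...) per clinical domain.

Because real patient data cannot ship with a package, `cdmaudit` also
includes a seeded synthetic CDM generator (`generate_clean()`), an
exact-count defect injector with a machine-readable truth manifest
(`apply_defects()`), and `build_paper_fixture()`, which regenerates the
headline results of a published audit of a ~1.8M-patient hospital CDM so
the whole pipeline can be verified end to end.

Datasets are read uniformly from either a directory of RFC-4180 CSV files
(one per table, empty field = missing) or a single-file SQLite database;
every assessment result is identical across the two dialects.

## Worked example

```r
library(cdmaudit)

# a clean two-year synthetic CDM for 1,000 persons, then plant defects
cfg <- generator_config(n_persons = 1000, seed = 42,
                        date_start = "2018-01", date_end = "2019-12")
d <- generate_clean(cfg, file.path(tempdir(), "demo_cdm"))
truth <- apply_defects(d, defect_plan(list(
  defect_spec("missing_value", "vocabulary", "vocabulary_version", exact_count = 5),
  defect_spec("unmapped_concept", "condition_occurrence", "condition_concept_id", rate = 0.05),
  defect_spec("temporal_gap", "drug_exposure", "drug_concept_id",
              params = list(date_column = "drug_exposure_start_date", gap_months = 3)),
  defect_spec("drop_table", "note")), seed = 7))

h <- open_dataset(d)
structural_report(h)
#> <structural_report> 39 tables: 38 available, 0 empty (0.0%), 1 not available (2.6%)
#>   total records in available tables: 33,740

df <- as.data.frame(run_rulebook(h))
df[df$flagged > 0, c("rule_id", "flagged", "total", "pct", "interpretation")]
#>                                             rule_id flagged total   pct   interpretation
#>               vocabulary.vocabulary_version.missing       5    12  41.7          deficit
#>           drug_exposure.monthly_count.discontinuity       1    13   7.7          deficit
#>  condition_occurrence.condition_concept_id.unmapped     182   983  18.5          deficit
#>    condition_occurrence.monthly_count.discontinuity       1    14   7.1          deficit
#>         concept_relationship.invalid_reason.missing     200   200 100.0 valid_by_default
#>                drug_strength.invalid_reason.missing      13    13 100.0 valid_by_default
```

Reading the output: the dropped `note` table surfaces as the one
`not_available` table (a free-text capture gap); the 5 planted missing
vocabulary versions are recovered exactly (5/12 rows, 41.7 %); 5 % of
condition rows were unmapped, which touches 182 of the 983 persons with
conditions (18.5 % — the unmapped check counts persons, not rows); the
three-month gap planted into one drug concept flags exactly that concept
in each drug table's monthly-count check; and the two `invalid_reason`
columns are fully "missing" yet reported `valid_by_default`, because NULL
is their design default. `truth` records exactly which rows and months
were altered, so every number above is verifiable.

`run_audit(h)` bundles all three components into a `completeness_report`
with interpreted findings, renderable as JSON, Markdown, or CSVs via
`render_report()`. The same surface is scriptable from a shell through the
installed launcher (`system.file("exec", "audit", package = "cdmaudit")`):
`audit run-all --dataset <dir> --out <dir>`, `audit fixture --scale 0.02
--seed 1 --out <dir>`, etc.

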