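---
title: "Auditing completeness of CDM-style clinical databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing completeness of CDM-style clinical databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmaudit)
```

## Scope and model

`cdmaudit` measures one data-quality dimension — completeness — for
relational clinical datasets in an OMOP-CDM-like layout, at three levels
that require different machinery and different interpretation:

* **structural**: is each expected table queryable, and does it hold
  records? The expectation is declarative (a schema manifest), because a
  database can only be incomplete *relative to* a stated schema. The
  bundled manifest lists the 39 tables of CDM v5.3; any manifest the YAML
  format can express may be substituted.
* **rule-based**: do the values present satisfy predefined completeness
  rules? Rules are data, not code: a rulebook file declares, per rule, a
  kind (`missing_or_special`, `unmapped_concept`,
  `temporal_discontinuity`, `value_range`), a target table/column,
  parameters, and a semantic class.
* **descriptive**: how are persons and records distributed across
  demographic and clinical categories? There is no gold-standard
  distribution; the profiles exist to be read against a study's target
  population, so the package computes counts and percentages but never
  scores them.

The central modeling commitment is that **detection and interpretation
are separate outputs**. A rule result carries both the measured
proportion and an interpretation: `deficit` for incompleteness-class
rules, `valid_by_default` for columns whose semantic class is
`expected_null` (e.g. `invalid_reason`, populated only when a concept is
deprecated — 100 % NULL there is evidence of validity, not
incompleteness), `not_applicable` when the denominator is empty or the
table absent. Structural findings carry machine-readable notes: an empty
*derived* table (`dose_era`) reads as "derivation scripts not executed"
rather than missing source data; an absent free-text table (`note`,
`note_nlp`) reads as a narrative-capture gap.

## Rule semantics and tunable parameters

**Missing/special values.** A value is flagged when it is missing or,
after whitespace trimming, empty, equal case-insensitively to a sentinel
in `{"NULL", "NA", "N/A", "UNKNOWN"}`, or composed solely of characters
from `{* - . ? # / \ + , _}`. Real audits phrase this check loosely
("missing or special character entries"), so both sets are explicit,
documented defaults, overridable per rule. The single internal missing
sentinel is `NA`: an SQL `NULL` and an empty delimited field are
indistinguishable downstream, which is what makes the two storage
dialects equivalent. A column that is *absent entirely* flags every
record (with warning `column-absent`): an uncollected column is the
strongest form of incompleteness, and the warning keeps it
distinguishable from 100 % row-level missingness.

**Unmapped concepts.** Missing, non-numeric, or zero concept ids are
unmapped (`0` is the reserved "No matching concept" sentinel). The
counting unit defaults to distinct persons (with at least one unmapped
record, over distinct persons in the table), matching how such findings
are reported in practice; `rows` is available per rule.

**Temporal discontinuities.** Events are bucketed by concept and calendar
month. Within each concept's first-to-last active month, consecutive
months are compared after inserting zero-count months (a concept recorded
in January and March was *silent* in February; skipping the silence would
hide exactly the gaps the check exists to find — the
`insert_zero_months = FALSE` switch restores observed-months-only
comparison for sensitivity analysis). A concept is flagged when
`|c_t − c_{t−1}| / c_{t−1} ≥ threshold` with `c_{t−1} > 0`; the default
threshold 1.0 is the conventional "100 % change in monthly count". Both
increases and decreases count, and a drop to zero is always a 100 %
change. A transition from zero to positive (onset) is counted and
reported in the detail but never flags: otherwise every concept would
flag at the first month after any silence, including its introduction
into clinical practice. Comparison uses a 1e-9 tolerance so exact-ratio
cases like 4→8 at threshold 1.0 are stable in floating point. Dates must
be ISO-8601 (`YYYY-MM-DD`); anything else is treated as missing, and a
wholly unparseable date column yields `not_applicable`.

**Value ranges.** Bounds are strict per their conventional phrasing
("maximum value should not be > 180"): a value equal to the bound passes.
Non-numeric values are skipped and counted separately rather than
coerced. Detail reports the per-concept extreme among violators.

**Ordering and determinism.** Results are returned in rulebook order;
concept lists in details are sorted by concept id ascending; profile ties
break by ascending concept id; findings sort by severity, then code, then
message. Two runs over the same inputs differ only in the report
timestamp.

**Percentages** everywhere are `100·k/n` rounded half away from zero to
one decimal (base R's round-half-even would print 12.75 → 12.7); this is
the rounding that reproduces published fractions such as 5/39 → 12.8 and
7/39 → 17.9. Zero denominators render as `not_applicable`, never as 0 %.

The report layer adds one explicitly tunable policy: an
incompleteness-class rule raises a `deficit` finding when its proportion
reaches `severity_threshold_pct` (default 5 %). Published audits call
rates in the 20–30 % range "substantial" without stating a cutoff, so the
cutoff here is visible configuration, not hidden policy.

## The synthetic generator and what it does and does not emulate

`generate_clean()` writes all 39 manifest tables for a configurable
cohort (`n_persons`, per-domain mean event counts, a month range,
a seed). "Clean" is a testable contract: every event references an
existing person, all concept ids come from the dictionary pools (never
0), all values are in range, every rule-targeted value column is
populated, and each concept's monthly event counts are engineered to be
near-constant — concepts with fewer than two events per month are placed
in a single month (one bucket, no transitions), all others are spread
with consecutive monthly counts differing by at most one. Consequently
the default rulebook flags zero records on every incompleteness rule, and
that is asserted, not assumed. The `expected_null` columns
(`invalid_reason`) are left in their default missing state, which is
their valid state.

`apply_defects()` plants defects with exact counts (or rates resolved
against the table size): missing values, special values, unmapped
concepts, out-of-range values, multi-month gaps cut out of one concept's
event series, emptied tables, dropped tables. Rows are sampled without
replacement, specs on the same column compose disjointly unless overlap
is requested, an infeasible spec aborts before any mutation is persisted,
and the returned truth manifest records exactly which rows/months were
altered. This closes the loop: the recovery tests assert that every rule
reports *precisely* the planted counts across randomized plans.

What the generator deliberately does **not** emulate: disease
trajectories, dosing logic, visit careflows, realistic code frequencies,
or correlations between domains. Realism is limited to the statistical
structure the assessment consumes. Passing tests therefore demonstrate
that the audit measures what is in the data; they do not demonstrate
performance on the messier failure modes of real EHRs (mixed date
dialects, encoding artifacts, semi-structured text), which the rule
parameters can be tuned to but which are not generated here.

## The reference fixture and its scaling policy

`build_paper_fixture()` regenerates, from published aggregate counts, a
synthetic counterpart of a ~1.8M-patient hospital CDM audit (2005–2023):
the 39-table availability split (7 empty, 5 not available, including the
free-text tables), eleven missing/special-value numerator/denominator
pairs, sex/race/ethnicity person counts (ethnicity entirely unmapped, as
expected for a non-US setting given the field's US-centric design),
visit-type person coverage, top condition/drug/measurement concepts by
person, and per-domain mapped-vocabulary row fractions. Only printed
aggregates are promised; names, dates and unconstrained ids come from
seeded pools.

Scaling policy (all of it recorded per count in the truth manifest):

* `scale` applies to the **cohort**: persons and person-linked counts,
  by half-up rounding (each realized count within one unit of the scaled
  target, with a floor of one record so availability classification is
  scale-invariant). Sex/race splits use largest-remainder apportionment
  so parts always sum to the person total.
* **Reference tables** (vocabulary: 124 rows, care_site: 1715, location:
  452, the concept tables) keep their printed sizes at every scale — a
  vocabulary does not shrink because the cohort does, and scaling a
  124-row table would destroy its printed 38/124 fraction.
* Tables whose full-scale size exceeds 20M rows (measurement 642M,
  drug_exposure 167M, procedure_occurrence 159M, concept_relationship
  55M) carry an extra configurable `big_table_downscale` (default
  1/1000) with all planted fractions preserved. Measurement and
  drug_exposure row totals are derived upward from the per-person
  top-concept memberships so that person coverage (e.g. hemoglobin in
  59.4 % of persons) and row-level vocabulary fractions (72.9 % LOINC)
  are planted simultaneously and consistently.

At cohort scale 0.2 (the acceptance script's setting: ~360k persons,
~3.1M observation rows, ~1.1M measurement rows, about a minute of
wall time) every published percentage reproduces at one-decimal
precision; the test suite uses scale 0.02 for the same checks in a few
seconds. These sizes are the package's chosen trade-off between fidelity
and desk-scale practicality.

## Storage dialects and degenerate inputs

Datasets are read through one contract from (a) a directory of RFC-4180
CSV files named `<table>.csv` with a header row, or (b) a single-file
SQLite database. Headers match case-insensitively; all values surface as
character with `NA` as the only missing sentinel; numeric parsing happens
per rule. Every assessment result is dialect-invariant by construction
and by test, with one documented exception: `table_bytes()` is an exact
file size for CSVs but an engine-reported, approximate (possibly `NA`)
relation size for SQLite, so volume profiles are only comparable within
one dialect. Absent tables are values (`not_available`), not errors, for
every assessor; absent columns warn and degrade as described above; empty
tables produce `not_applicable` rule results and are excluded from volume
fractions. Tables present in the data but absent from the manifest are
listed separately as unexpected, never silently classified.

## Known limitations

* Date handling is ISO-8601 only; other dialects must be normalized
  upstream (nonconforming dates are counted as missing, which is visible
  in the temporal detail rather than silent).
* The temporal detector compares calendar months; weekly or seasonal
  granularity is out of scope.
* The default manifest and rulebook reconstruct a conventional CDM v5.3
  audit configuration; site-specific audits should review both files
  rather than treat them as normative.
* Profiling has no statistical testing of distribution balance by design:
  the right reference distribution depends on the intended use.
* SQLite is the only SQL engine bundled; other engines would need a
  driver behind the same dataset contract.
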