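#' @title Reference audit fixture
#' @description Builds a synthetic dataset that regenerates the headline
#' numerator/denominator pairs of a large single-hospital EHR completeness
#' audit (a ~1.8M-patient Korean tertiary-hospital CDM spanning 2005-2023):
#' the structural availability split (7/39 empty, 5/39 not available), the
#' eleven missing/special-value table-column pairs, demographic and
#' visit-type person counts, top clinical concepts by person, and the
#' per-domain mapped-vocabulary row fractions. Running the audit on the
#' fixture must reproduce every one of those printed percentages.
#' @name fixture
NULL

# published full-scale counts the fixture regenerates
paper_counts <- function() {
  list(
    persons = 1798153, male = 886489, female = 911664,
    race_korean = 1739628, race_unmapped = 58525,
    visit = c(`9202` = 1444995, `9203` = 687254, `9201` = 494492,
              `9205` = 272061, `32037` = 46651),
    cond_top = c(`4027663` = 134783, `320128` = 115262, `4112343` = 111126),
    cond_background_each = 50000,
    drug_top = c(`21600001` = 360530, `21600002` = 358831, `21600003` = 282130),
    meas_top = c(`3000963` = 1068822, `3006923` = 1037714,
                 `3013721` = 1037534, `3016723` = 1005168),
    vocab_rows = 124, vocab_version_missing = 38,
    care_site_rows = 1715, care_site_pos_missing = 28, care_site_name_special = 26,
    location_rows = 452, location_state_missing = 2,
    death_rows = 34330, death_cause_missing = 117,
    obs_rows = 15313287, obs_value_missing = 3643581,
    obs_vocab = c(SNOMED = 14833557, LOINC = 399874, Other = 80032),
    meas_rows = 642623715, meas_unit_missing = 25583622, meas_value_special = 1910233,
    meas_vocab = c(LOINC = 468274853, SNOMED = 116316640,
                   `OMOP Extension` = 52320453, Other = 5726710),
    drug_rows = 166706078, drug_dose_missing = 232,
    drug_vocab = c(`RxNorm Extension` = 143512501, RxNorm = 16810245,
                   `OMOP Extension` = 4026859, Other = 2352875),
    proc_rows = 159007634,
    proc_vocab = c(`OMOP Extension` = 85344562, SNOMED = 69604840, Other = 4065510),
    cr_rows = 55082424, ds_rows = 2935461, ds_invalid_missing = 2932914,
    specimen_rows = 200000,
    empty_tables = c("metadata", "dose_era", "cohort", "cohort_attribute",
                     "cost", "payer_plan_period", "device_exposure"),
    absent_tables = c("note", "note_nlp", "attribute_definition",
                      "cohort_definition", "concept_synonym"))
}

#' Build the reference audit fixture
#'
#' `scale` scales the cohort: persons and every person-linked event or row
#' count, by half-up rounding of `scale * full_count` (so each realized
#' count is within 1 of the scaled target). Reference and site tables whose
#' size does not depend on cohort size (vocabulary 124 rows, care_site
#' 1715, location 452, the concept tables) keep their full printed sizes at
#' every scale -- a vocabulary does not shrink because the cohort does.
#' Tables whose full-scale row count exceeds `big_table_threshold` rows
#' (measurement, drug_exposure, procedure_occurrence,
#' concept_relationship) additionally carry `big_table_downscale`, with all
#' planted fractions preserved; measurement and drug_exposure row totals
#' are floored by the per-person top-concept memberships so person coverage
#' and vocabulary fractions are planted simultaneously. Every available
#' table keeps at least one record so the structural classification is
#' scale-invariant.
#'
#' @param dir Target locator.
#' @param scale Cohort scale in (0, 1].
#' @param seed RNG seed; output is byte-identical under a fixed seed.
#' @param dialect Storage dialect.
#' @param big_table_downscale Extra factor for very large tables.
#' @param big_table_threshold Full-scale row count above which the extra
#'   factor applies.
#' @param dictionary Concept pools, a [concept_dictionary()].
#' @return Invisibly, a list with `locator` and `truth`. The truth manifest
#'   records every planted count with its full-scale base and scaling class
#'   (`cohort`, `reference`, `big_table`, or `derived`), plus the expected
#'   flagged/total pair for each planted rule outcome.
#' @export
build_paper_fixture <- function(dir = tempfile("cdm_fixture_"), scale = 1.0,
                                seed = 1L, dialect = "delimited_directory",
                                big_table_downscale = 1 / 1000,
                                big_table_threshold = 2e7,
                                dictionary = default_dictionary()) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1)
    validation_error("scale must be in (0, 1]")
  dialect <- match.arg(dialect, DIALECTS)
  px <- paper_counts()
  dict <- dictionary
  months <- seq(parse_month("2005-01"), parse_month("2023-12"))
  emit <- make_emitter(dir, dialect)

  counts <- list()
  reg <- function(name, count, base, scaling) {
    counts[[name]] <<- list(count = as.numeric(count), base = as.numeric(base),
                            scaling = scaling)
  }
  expected <- list()
  exp_rule <- function(rule_id, flagged, total) {
    expected[[rule_id]] <<- list(flagged = as.numeric(flagged), total = as.numeric(total))
  }
  sc <- function(n) max(1L, scale_count(n, scale))      # cohort-scaled, floor 1
  sc0 <- function(n) scale_count(n, scale)              # cohort-scaled, may be 0
  bigf <- scale * big_table_downscale

  with_seed(seed, {
    ## person -------------------------------------------------------------
    P <- sc(px$persons)
    sex_n <- apportion(c(px$male, px$female), P)
    race_n <- apportion(c(px$race_korean, px$race_unmapped), P)
    pid <- as.character(seq_len(P))
    gender <- sample(rep(c("8507", "8532"), sex_n))
    race <- sample(rep(c("38003585", "0"), race_n))
    emit("person", data.table::data.table(
      person_id = pid, gender_concept_id = gender,
      year_of_birth = as.character(sample(1930:2015, P, replace = TRUE)),
      race_concept_id = race, ethnicity_concept_id = "0",
      gender_source_value = data.table::fifelse(gender == "8507", "M", "F"),
      race_source_value = data.table::fifelse(race == "0", "Other", "Korean"),
      ethnicity_source_value = NA_character_))
    reg("persons", P, px$persons, "cohort")
    reg("male", sex_n[1], px$male, "cohort")
    reg("female", sex_n[2], px$female, "cohort")
    reg("race_korean", race_n[1], px$race_korean, "cohort")
    reg("race_unmapped", race_n[2], px$race_unmapped, "cohort")
    exp_rule("person.race_concept_id.unmapped", race_n[2], P)
    exp_rule("person.ethnicity_concept_id.unmapped", P, P)

    emit("observation_period", data.table::data.table(
      observation_period_id = pid, person_id = pid,
      observation_period_start_date = "2005-01-01",
      observation_period_end_date = "2023-12-28"))

    ## visit_occurrence: one row per (person, visit type) membership -------
    vkeep <- lapply(names(px$visit), function(vc) {
      k <- sc(px$visit[[vc]])
      reg(paste0("visit_", vc), k, px$visit[[vc]], "cohort")
      data.table::data.table(person_id = as.character(sample.int(P, k)),
                             visit_concept_id = vc)
    })
    vis <- data.table::rbindlist(vkeep)
    vis[, visit_start_date := spread_concept_dates(visit_concept_id, months)]
    emit("visit_occurrence", data.table::data.table(
      visit_occurrence_id = as.character(seq_len(nrow(vis))),
      person_id = vis$person_id, visit_concept_id = vis$visit_concept_id,
      visit_start_date = vis$visit_start_date,
      visit_end_date = vis$visit_start_date, visit_source_value = "V"))
    nvd <- max(1L, nrow(vis) %/% 20L)
    emit("visit_detail", data.table::data.table(
      visit_detail_id = as.character(seq_len(nvd)),
      person_id = vis$person_id[seq_len(nvd)],
      visit_detail_concept_id = vis$visit_concept_id[seq_len(nvd)],
      visit_detail_start_date = vis$visit_start_date[seq_len(nvd)]))
    rm(vis, vkeep)

    ## condition_occurrence / condition_era --------------------------------
    cond_pool <- concept_pool(dict, "Condition")
    bg_pool <- setdiff(cond_pool, names(px$cond_top))
    ckeep <- lapply(names(px$cond_top), function(cc) {
      k <- sc(px$cond_top[[cc]])
      reg(paste0("cond_top_", cc), k, px$cond_top[[cc]], "cohort")
      data.table::data.table(person_id = as.character(sample.int(P, k)),
                             condition_concept_id = cc)
    })
    cbg <- lapply(bg_pool, function(cc) {
      k <- sc(px$cond_background_each)
      data.table::data.table(person_id = as.character(sample.int(P, k)),
                             condition_concept_id = cc)
    })
    cond <- data.table::rbindlist(c(ckeep, cbg))
    cond[, condition_start_date := spread_concept_dates(condition_concept_id, months)]
    emit("condition_occurrence", data.table::data.table(
      condition_occurrence_id = as.character(seq_len(nrow(cond))),
      person_id = cond$person_id, condition_concept_id = cond$condition_concept_id,
      condition_start_date = cond$condition_start_date,
      condition_source_value = paste0("K", cond$condition_concept_id)))
    emit("condition_era", data.table::data.table(
      condition_era_id = as.character(seq_len(nrow(cond))),
      person_id = cond$person_id, condition_concept_id = cond$condition_concept_id,
      condition_era_start_date = cond$condition_start_date,
      condition_era_end_date = cond$condition_start_date))
    rm(cond, ckeep, cbg)

    ## drug_exposure: top-drug memberships + filler at Table-2 fractions ---
    memb_d <- lapply(names(px$drug_top), function(dc) {
      k <- sc(px$drug_top[[dc]])
      reg(paste0("drug_top_", dc), k, px$drug_top[[dc]], "cohort")
      data.table::data.table(person_id = as.character(sample.int(P, k)),
                             drug_concept_id = dc)
    })
    memb_d <- data.table::rbindlist(memb_d)
    T_drug <- scale_count(nrow(memb_d) * px$drug_rows / px$drug_vocab[["RxNorm Extension"]], 1)
    filler_n <- max(0L, T_drug - nrow(memb_d))
    fill_v <- apportion(px$drug_vocab[c("RxNorm", "OMOP Extension", "Other")], filler_n)
    fill_pools <- list(concept_pool(dict, "Drug", "RxNorm"),
                       concept_pool(dict, "Drug", "OMOP Extension"),
                       concept_pool(dict, "Drug", "EDI"))
    fill_cc <- unlist(lapply(seq_along(fill_pools), function(j)
      rep(fill_pools[[j]], apportion(rep(1, length(fill_pools[[j]])), fill_v[j]))))
    drug <- rbind(memb_d, data.table::data.table(
      person_id = as.character(sample.int(P, filler_n, replace = TRUE)),
      drug_concept_id = fill_cc))
    drug[, drug_exposure_start_date := spread_concept_dates(drug_concept_id, months)]
    k_dose <- scale_count(px$drug_dose_missing * nrow(drug) / px$drug_rows, 1)
    dose_unit <- rep("mg", nrow(drug))
    if (k_dose > 0) dose_unit[sample.int(nrow(drug), k_dose)] <- NA_character_
    emit("drug_exposure", data.table::data.table(
      drug_exposure_id = as.character(seq_len(nrow(drug))),
      person_id = drug$person_id, drug_concept_id = drug$drug_concept_id,
      drug_exposure_start_date = drug$drug_exposure_start_date,
      days_supply = as.character(sample(c(3L, 7L, 14L, 30L, 60L, 90L),
                                        nrow(drug), replace = TRUE)),
      quantity = as.character(sample(c(1L, 2L, 5L, 10L, 30L, 60L, 100L),
                                     nrow(drug), replace = TRUE)),
      dose_unit_source_value = dose_unit,
      drug_source_value = paste0("D", drug$drug_concept_id)))
    reg("drug_rows", nrow(drug), px$drug_rows, "derived")
    reg("drug_dose_missing", k_dose, px$drug_dose_missing, "derived")
    exp_rule("drug_exposure.dose_unit_source_value.missing", k_dose, nrow(drug))
    exp_rule("drug_exposure.days_supply.range", 0, nrow(drug))
    exp_rule("drug_exposure.quantity.range", 0, nrow(drug))
    emit("drug_era", data.table::data.table(
      drug_era_id = as.character(seq_len(nrow(memb_d))),
      person_id = memb_d$person_id, drug_concept_id = memb_d$drug_concept_id,
      drug_era_start_date = spread_concept_dates(memb_d$drug_concept_id, months),
      drug_era_end_date = NA_character_))
    rm(drug, memb_d, fill_cc)

    ## measurement ---------------------------------------------------------
    memb_m <- lapply(names(px$meas_top), function(mc) {
      k <- sc(px$meas_top[[mc]])
      reg(paste0("meas_top_", mc), k, px$meas_top[[mc]], "cohort")
      data.table::data.table(person_id = as.character(sample.int(P, k)),
                             measurement_concept_id = mc)
    })
    memb_m <- data.table::rbindlist(memb_m)
    T_meas <- scale_count(nrow(memb_m) * px$meas_rows / px$meas_vocab[["LOINC"]], 1)
    filler_n <- max(0L, T_meas - nrow(memb_m))
    fill_v <- apportion(px$meas_vocab[c("SNOMED", "OMOP Extension", "Other")], filler_n)
    fill_pools <- list(concept_pool(dict, "Measurement", "SNOMED"),
                       concept_pool(dict, "Measurement", "OMOP Extension"),
                       concept_pool(dict, "Measurement", c("EDI", "KCD7")))
    fill_cc <- unlist(lapply(seq_along(fill_pools), function(j)
      rep(fill_pools[[j]], apportion(rep(1, length(fill_pools[[j]])), fill_v[j]))))
    meas <- rbind(memb_m, data.table::data.table(
      person_id = as.character(sample.int(P, filler_n, replace = TRUE)),
      measurement_concept_id = fill_cc))
    n_meas <- nrow(meas)
    k_unit <- scale_count(px$meas_unit_missing * n_meas / px$meas_rows, 1)
    k_val <- scale_count(px$meas_value_special * n_meas / px$meas_rows, 1)
    unit <- rep("mg/dL", n_meas)
    if (k_unit > 0) unit[sample.int(n_meas, k_unit)] <- NA_character_
    val <- as.character(round(stats::runif(n_meas, 1, 200), 1))
    if (k_val > 0) val[sample.int(n_meas, k_val)] <- "*"
    emit("measurement", data.table::data.table(
      measurement_id = as.character(seq_len(n_meas)),
      person_id = meas$person_id,
      measurement_concept_id = meas$measurement_concept_id,
      measurement_date = spread_concept_dates(meas$measurement_concept_id, months),
      value_as_number = val, unit_source_value = unit, value_source_value = val))
    reg("meas_rows", n_meas, px$meas_rows, "derived")
    reg("meas_unit_missing", k_unit, px$meas_unit_missing, "derived")
    reg("meas_value_special", k_val, px$meas_value_special, "derived")
    exp_rule("measurement.unit_source_value.missing", k_unit, n_meas)
    exp_rule("measurement.value_source_value.missing", k_val, n_meas)
    rm(meas, memb_m, fill_cc, unit, val)

    ## observation ---------------------------------------------------------
    T_obs <- sc(px$obs_rows)
    ob_v <- apportion(px$obs_vocab, T_obs)
    ob_pools <- list(concept_pool(dict, "Observation", "SNOMED"),
                     concept_pool(dict, "Observation", "LOINC"),
                     concept_pool(dict, "Observation", c("EDI", "KCD7")))
    ob_cc <- unlist(lapply(seq_along(ob_pools), function(j)
      rep(ob_pools[[j]], apportion(rep(1, length(ob_pools[[j]])), ob_v[j]))))
    k_obs <- min(sc0(px$obs_value_missing), T_obs)
    vals <- sample(c("positive", "negative", "normal finding", "abnormal finding"),
                   T_obs, replace = TRUE)
    if (k_obs > 0) vals[sample.int(T_obs, k_obs)] <- NA_character_
    emit("observation", data.table::data.table(
      observation_id = as.character(seq_len(T_obs)),
      person_id = as.character(sample.int(P, T_obs, replace = TRUE)),
      observation_concept_id = ob_cc,
      observation_date = spread_concept_dates(ob_cc, months),
      value_as_string = vals,
      observation_source_value = paste0("O", ob_cc)))
    reg("obs_rows", T_obs, px$obs_rows, "cohort")
    reg("obs_value_missing", k_obs, px$obs_value_missing, "cohort")
    exp_rule("observation.value_as_string.missing", k_obs, T_obs)
    rm(ob_cc, vals)

    ## procedure_occurrence ------------------------------------------------
    T_proc <- max(1L, scale_count(px$proc_rows, bigf))
    pr_v <- apportion(px$proc_vocab, T_proc)
    pr_pools <- list(concept_pool(dict, "Procedure", "OMOP Extension"),
                     concept_pool(dict, "Procedure", "SNOMED"),
                     concept_pool(dict, "Procedure", "EDI"))
    pr_cc <- unlist(lapply(seq_along(pr_pools), function(j)
      rep(pr_pools[[j]], apportion(rep(1, length(pr_pools[[j]])), pr_v[j]))))
    emit("procedure_occurrence", data.table::data.table(
      procedure_occurrence_id = as.character(seq_len(T_proc)),
      person_id = as.character(sample.int(P, T_proc, replace = TRUE)),
      procedure_concept_id = pr_cc,
      procedure_date = spread_concept_dates(pr_cc, months),
      procedure_source_value = paste0("P", pr_cc)))
    reg("proc_rows", T_proc, px$proc_rows, "big_table")
    rm(pr_cc)

    ## death ---------------------------------------------------------------
    D <- sc(px$death_rows)
    k_death <- min(sc0(px$death_cause_missing), D)
    cause_src <- paste0("I", sample(10:99, D, replace = TRUE))
    if (k_death > 0) cause_src[sample.int(D, k_death)] <- NA_character_
    emit("death", data.table::data.table(
      person_id = as.character(sample.int(P, D)),
      death_date = spread_concept_dates(rep("death", D), months),
      cause_concept_id = sample(cond_pool, D, replace = TRUE),
      cause_source_value = cause_src))
    reg("death_rows", D, px$death_rows, "cohort")
    reg("death_cause_missing", k_death, px$death_cause_missing, "cohort")
    exp_rule("death.cause_source_value.missing", k_death, D)

    ## specimen ------------------------------------------------------------
    n_spec <- sc(px$specimen_rows)
    emit("specimen", data.table::data.table(
      specimen_id = as.character(seq_len(n_spec)),
      person_id = as.character(sample.int(P, n_spec, replace = TRUE)),
      specimen_concept_id = "4001225",
      specimen_date = spread_concept_dates(rep("4001225", n_spec), months)))

    ## reference / site tables (printed sizes, scale-invariant) ------------
    vocabs <- sort(unique(dict$entries$vocabulary_id))
    vocab_ids <- c(vocabs, sprintf("VOCAB_%03d", seq_len(px$vocab_rows - length(vocabs))))
    vv <- paste0("v", format(2000 + seq_along(vocab_ids) %% 24), ".1")
    vv[sample.int(px$vocab_rows, px$vocab_version_missing)] <- NA_character_
    emit("vocabulary", data.table::data.table(
      vocabulary_id = vocab_ids, vocabulary_name = paste(vocab_ids, "vocabulary"),
      vocabulary_reference = "synthetic", vocabulary_version = vv))
    reg("vocab_rows", px$vocab_rows, px$vocab_rows, "reference")
    reg("vocab_version_missing", px$vocab_version_missing, px$vocab_version_missing, "reference")
    exp_rule("vocabulary.vocabulary_version.missing", px$vocab_version_missing, px$vocab_rows)

    cs_name <- sprintf("Care site %04d", seq_len(px$care_site_rows))
    cs_name[sample.int(px$care_site_rows, px$care_site_name_special)] <- "*"
    cs_pos <- rep(c("OP", "IP", "ER"), length.out = px$care_site_rows)
    cs_pos[sample.int(px$care_site_rows, px$care_site_pos_missing)] <- NA_character_
    emit("care_site", data.table::data.table(
      care_site_id = as.character(seq_len(px$care_site_rows)),
      care_site_name = cs_name, place_of_service_concept_id = "9202",
      place_of_service_source_value = cs_pos))
    reg("care_site_rows", px$care_site_rows, px$care_site_rows, "reference")
    exp_rule("care_site.place_of_service_source_value.missing",
             px$care_site_pos_missing, px$care_site_rows)
    exp_rule("care_site.care_site_name.missing",
             px$care_site_name_special, px$care_site_rows)

    st <- rep(c("Incheon", "Seoul", "Gyeonggi", "Busan", "Daegu", "Daejeon",
                "Gwangju", "Ulsan", "Gangwon", "Jeju"),
              length.out = px$location_rows)
    st[sample.int(px$location_rows, px$location_state_missing)] <- NA_character_
    emit("location", data.table::data.table(
      location_id = as.character(seq_len(px$location_rows)),
      city = paste("City", seq_len(px$location_rows)), state = st,
      zip = sprintf("%05d", seq_len(px$location_rows)),
      location_source_value = paste0("L", seq_len(px$location_rows))))
    reg("location_rows", px$location_rows, px$location_rows, "reference")
    exp_rule("location.state.missing", px$location_state_missing, px$location_rows)

    ## vocabulary-family content tables -------------------------------------
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
    emit("relationship", data.table::data.table(
      relationship_id = c("Maps to", "Mapped from", "Is a"),
      relationship_name = c("Maps to", "Mapped from", "Is a")))
    emit("concept_ancestor", data.table::data.table(
      ancestor_concept_id = cz$concept_id, descendant_concept_id = cz$concept_id))
    emit("source_to_concept_map", data.table::data.table(
      source_code = paste0("S", cz$concept_id), source_concept_id = "0",
      target_concept_id = cz$concept_id))

    T_cr <- max(1L, scale_count(px$cr_rows, bigf))
    emit("concept_relationship", data.table::data.table(
      concept_id_1 = sample(cz$concept_id, T_cr, replace = TRUE),
      concept_id_2 = sample(cz$concept_id, T_cr, replace = TRUE),
      relationship_id = "Maps to", valid_start_date = "1970-01-01",
      valid_end_date = "2099-12-31", invalid_reason = NA_character_))
    reg("cr_rows", T_cr, px$cr_rows, "big_table")
    exp_rule("concept_relationship.invalid_reason.missing", T_cr, T_cr)

    T_ds <- sc(px$ds_rows)
    k_ds <- min(sc0(px$ds_invalid_missing), T_ds)
    inv <- rep("D", T_ds)
    if (k_ds > 0) inv[sample.int(T_ds, k_ds)] <- NA_character_
    dr_pool <- concept_pool(dict, "Drug")
    emit("drug_strength", data.table::data.table(
      drug_concept_id = sample(dr_pool, T_ds, replace = TRUE),
      ingredient_concept_id = sample(dr_pool, T_ds, replace = TRUE),
      amount_value = "100", invalid_reason = inv))
    reg("ds_rows", T_ds, px$ds_rows, "cohort")
    reg("ds_invalid_missing", k_ds, px$ds_invalid_missing, "cohort")
    exp_rule("drug_strength.invalid_reason.missing", k_ds, T_ds)

    ## small operational tables ---------------------------------------------
    emit("fact_relationship", data.table::data.table(
      domain_concept_id_1 = "21", fact_id_1 = "1",
      domain_concept_id_2 = "27", fact_id_2 = "1",
      relationship_concept_id = "44818890"))
    emit("provider", data.table::data.table(
      provider_id = as.character(1:50),
      provider_name = sprintf("Provider %02d", 1:50),
      specialty_concept_id = "38004446"))
    emit("cdm_source", data.table::data.table(
      cdm_source_name = "cdmaudit reference fixture", cdm_version = "v5.3",
      vocabulary_version = "synthetic-2023"))

    ## empty tables (header only) and absent tables -------------------------
    empty_schemas <- list(
      metadata = c("metadata_concept_id", "name", "value_as_string"),
      dose_era = c("dose_era_id", "person_id", "drug_concept_id", "dose_value"),
      cohort = c("cohort_definition_id", "subject_id", "cohort_start_date"),
      cohort_attribute = c("cohort_definition_id", "subject_id",
                           "attribute_definition_id", "value_as_number"),
      cost = c("cost_id", "cost_event_id", "total_charge"),
      payer_plan_period = c("payer_plan_period_id", "person_id",
                            "payer_plan_period_start_date"),
      device_exposure = c("device_exposure_id", "person_id",
                          "device_concept_id", "device_exposure_start_date"))
    for (nm in px$empty_tables) emit(nm, empty_cols(empty_schemas[[nm]]))
  })

  truth <- structure(list(
    scale = scale, seed = as.integer(seed),
    big_table_downscale = big_table_downscale,
    big_table_threshold = big_table_threshold,
    counts = counts, expected_rules = expected,
    empty_tables = px$empty_tables, absent_tables = px$absent_tables,
    n_tables = 39L), class = "fixture_truth")
  invisible(list(locator = dir, truth = truth))
}
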