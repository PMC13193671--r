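# Default completeness rulebook: missing/special-value checks for the
# standard table-column pairs, person-level unmapped-concept checks,
# monthly-count discontinuity checks (100% change threshold), and the two
# prescription value-range checks. Rules are grouped by table so a run
# streams each table once. User-replaceable via load_rulebook().
rules:
  - {id: vocabulary.vocabulary_version.missing, kind: missing_or_special,
     table: vocabulary, column: vocabulary_version}
  - {id: observation.value_as_string.missing, kind: missing_or_special,
     table: observation, column: value_as_string}
  - {id: observation.observation_concept_id.unmapped, kind: unmapped_concept,
     table: observation, column: observation_concept_id}
  - {id: observation.monthly_count.discontinuity, kind: temporal_discontinuity,
     table: observation, column: observation_concept_id,
     params: {date_column: observation_date}}
  - {id: measurement.unit_source_value.missing, kind: missing_or_special,
     table: measurement, column: unit_source_value}
  - {id: measurement.value_source_value.missing, kind: missing_or_special,
     table: measurement, column: value_source_value}
  - {id: care_site.place_of_service_source_value.missing, kind: missing_or_special,
     table: care_site, column: place_of_service_source_value}
  - {id: care_site.care_site_name.missing, kind: missing_or_special,
     table: care_site, column: care_site_name}
  - {id: location.state.missing, kind: missing_or_special,
     table: location, column: state}
  - {id: death.cause_source_value.missing, kind: missing_or_special,
     table: death, column: cause_source_value}
  - {id: death.cause_concept_id.unmapped, kind: unmapped_concept,
     table: death, column: cause_concept_id}
  - {id: drug_exposure.dose_unit_source_value.missing, kind: missing_or_special,
     table: drug_exposure, column: dose_unit_source_value}
  - {id: drug_exposure.drug_concept_id.unmapped, kind: unmapped_concept,
     table: drug_exposure, column: drug_concept_id}
  - {id: drug_exposure.monthly_count.discontinuity, kind: temporal_discontinuity,
     table: drug_exposure, column: drug_concept_id,
     params: {date_column: drug_exposure_start_date}}
  - {id: drug_exposure.days_supply.range, kind: value_range,
     table: drug_exposure, column: days_supply,
     params: {bound: 180, direction: max_le, group_column: drug_concept_id}}
  - {id: drug_exposure.quantity.range, kind: value_range,
     table: drug_exposure, column: quantity,
     params: {bound: 600, direction: max_le, group_column: drug_concept_id}}
  - {id: drug_era.monthly_count.discontinuity, kind: temporal_discontinuity,
     table: drug_era, column: drug_concept_id,
     params: {date_column: drug_era_start_date}}
  - {id: person.race_concept_id.unmapped, kind: unmapped_concept,
     table: person, column: race_concept_id}
  - {id: person.ethnicity_concept_id.unmapped, kind: unmapped_concept,
     table: person, column: ethnicity_concept_id}
  - {id: procedure_occurrence.procedure_concept_id.unmapped, kind: unmapped_concept,
     table: procedure_occurrence, column: procedure_concept_id}
  - {id: procedure_occurrence.monthly_count.discontinuity, kind: temporal_discontinuity,
     table: procedure_occurrence, column: procedure_concept_id,
     params: {date_column: procedure_date}}
  - {id: condition_occurrence.condition_concept_id.unmapped, kind: unmapped_concept,
     table: condition_occurrence, column: condition_concept_id}
  - {id: condition_occurrence.monthly_count.discontinuity, kind: temporal_discontinuity,
     table: condition_occurrence, column: condition_concept_id,
     params: {date_column: condition_start_date}}
  - {id: condition_era.condition_concept_id.unmapped, kind: unmapped_concept,
     table: condition_era, column: condition_concept_id}
  - {id: condition_era.monthly_count.discontinuity, kind: temporal_discontinuity,
     table: condition_era, column: condition_concept_id,
     params: {date_column: condition_era_start_date}}
  - {id: concept_relationship.invalid_reason.missing, kind: missing_or_special,
     table: concept_relationship, column: invalid_reason,
     semantic_class: expected_null}
  - {id: drug_strength.invalid_reason.missing, kind: missing_or_special,
     table: drug_strength, column: invalid_reason,
     semantic_class: expected_null}
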