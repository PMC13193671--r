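concept_id,concept_name,vocabulary_id,domain_id
0,No matching concept,None,Metadata
8507,MALE,Gender,Gender
8532,FEMALE,Gender,Gender
38003585,Korean,Race,Race
38003563,Hispanic or Latino,Ethnicity,Ethnicity
38003564,Not Hispanic or Latino,Ethnicity,Ethnicity
9201,Inpatient visit,Visit,Visit
9202,Outpatient visit,Visit,Visit
9203,Emergency room visit,Visit,Visit
9205,Health examination,Visit,Visit
32037,Intensive care,Visit,Visit
4027663,Inflammatory disorder of the digestive tract,SNOMED,Condition
320128,Essential hypertension,SNOMED,Condition
4112343,Gastritis,SNOMED,Condition
201826,Type 2 diabetes mellitus,SNOMED,Condition
317009,Asthma,SNOMED,Condition
260125,Acute upper respiratory infection,SNOMED,Condition
194133,Low back pain,SNOMED,Condition
432867,Hyperlipidemia,SNOMED,Condition
4184252,Allergic rhinitis,SNOMED,Condition
80180,Osteoarthritis,SNOMED,Condition
439777,Anemia,SNOMED,Condition
436962,Insomnia,SNOMED,Condition
440383,Depressive disorder,SNOMED,Condition
21600001,100-mL sodium chloride 9-mg/mL injectable solution (JW NS),RxNorm Extension,Drug
21600002,"10,000-mL oxygen gas for inhalation",RxNorm Extension,Drug
21600003,Artemisia argyi leaf extract 60-mg oral tablet (Stillen),RxNorm Extension,Drug
21600004,Pelargonium sidoides root extract 90-mL oral syrup,RxNorm Extension,Drug
21600005,Bearberry leaf dry extract 105-mg oral tablet,RxNorm Extension,Drug
1127433,Acetaminophen 650 MG Oral Tablet,RxNorm,Drug
197361,Amlodipine 5 MG Oral Tablet,RxNorm,Drug
1545996,Atorvastatin 20 MG Oral Tablet,RxNorm,Drug
1560171,Metformin 500 MG Oral Tablet,RxNorm,Drug
19078924,Omeprazole 20 MG Oral Capsule,RxNorm,Drug
600001,Normal saline irrigation solution (local),OMOP Extension,Drug
600002,Compounded analgesic mixture (local),OMOP Extension,Drug
900001,Unclassified local drug code,EDI,Drug
3000963,Hemoglobin (mass per volume) in blood by calculation,LOINC,Measurement
3006923,Alanine aminotransferase (enzymatic activity per volume) in serum or plasma,LOINC,Measurement
3013721,Aspartate aminotransferase (enzymatic activity per volume) in serum or plasma,LOINC,Measurement
3016723,Creatinine (mass per volume) in serum or plasma,LOINC,Measurement
3004249,Systolic blood pressure,LOINC,Measurement
3012888,Diastolic blood pressure,LOINC,Measurement
3024561,Albumin (mass per volume) in serum or plasma,LOINC,Measurement
3019550,Sodium (moles per volume) in serum or plasma,LOINC,Measurement
4301868,Pulse rate,SNOMED,Measurement
4302666,Body temperature,SNOMED,Measurement
4152194,Blood pressure panel,SNOMED,Measurement
706001,Local laboratory panel result,OMOP Extension,Measurement
706002,Derived clinical index,OMOP Extension,Measurement
901001,Local laboratory code,EDI,Measurement
901002,Local claim code,KCD7,Measurement
4005823,Tobacco smoking status,SNOMED,Observation
4052017,Alcohol intake pattern,SNOMED,Observation
4058431,Family history of clinical disorder,SNOMED,Observation
4059468,Occupational status,SNOMED,Observation
4053609,Dietary assessment finding,SNOMED,Observation
3025315,Body weight,LOINC,Observation
3036277,Body height,LOINC,Observation
902001,Local survey item,EDI,Observation
902002,Local registry item,KCD7,Observation
720001,Local endoscopy procedure,OMOP Extension,Procedure
720002,Local imaging procedure,OMOP Extension,Procedure
720003,Local infusion procedure,OMOP Extension,Procedure
4163872,Colonoscopy,SNOMED,Procedure
4198190,Appendectomy,SNOMED,Procedure
4133311,Electrocardiogram,SNOMED,Procedure
903001,Local procedure code,EDI,Procedure
4001225,Blood specimen,SNOMED,Specimen
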