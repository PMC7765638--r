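# Default PCOS phenotyping configuration.
#
# The exclusion set below is a SYNTHETIC PLACEHOLDER listing common PCOS
# mimics (congenital adrenal hyperplasia, Cushing syndrome,
# androgen-secreting neoplasm, hyperprolactinemia, thyroid dysfunction).
# Real deployments must substitute their institution's exclusion list.
code_sets:
  polycystic_ovaries:
    - {pattern: "256.4", version: ICD9, mode: exact}
    - {pattern: "E28.2", version: ICD10, mode: exact}
  hirsutism:
    - {pattern: "704.1", version: ICD9, mode: exact}
    - {pattern: "L68.0", version: ICD10, mode: exact}
  irregular_menses:
    - {pattern: "626", version: ICD9, mode: prefix}
    - {pattern: "N91", version: ICD10, mode: prefix}
    - {pattern: "N92.5", version: ICD10, mode: exact}
    - {pattern: "N92.6", version: ICD10, mode: exact}
  pcos_exclusions:
    - {pattern: "255.2", version: ICD9, mode: exact}
    - {pattern: "E25", version: ICD10, mode: prefix}
    - {pattern: "255.0", version: ICD9, mode: exact}
    - {pattern: "E24", version: ICD10, mode: prefix}
    - {pattern: "183.0", version: ICD9, mode: exact}
    - {pattern: "C56", version: ICD10, mode: prefix}
    - {pattern: "253.1", version: ICD9, mode: exact}
    - {pattern: "E22.1", version: ICD10, mode: exact}
    - {pattern: "244.9", version: ICD9, mode: exact}
    - {pattern: "E03.9", version: ICD10, mode: exact}
    - {pattern: "242.9", version: ICD9, mode: exact}
    - {pattern: "E05.9", version: ICD10, mode: exact}
algorithms:
  keyword_strict:
    inclusion: "polycystic_ovaries | (hirsutism & irregular_menses)"
    exclusion: pcos_exclusions
    keyword:
      required: true
      keywords: ["polycystic ovaries", "PCOS", "PCO"]
      note_types:
        - outpatient note
        - gynecology clinic visit
        - nursing report
        - endocrine and diabetes clinic visit
        - pediatric endocrinology patient visit
        - reproductive endocrinology clinic visit
    age_range: [11, 44]
  coded_strict:
    inclusion: "polycystic_ovaries | (hirsutism & irregular_menses)"
    exclusion: pcos_exclusions
    age_range: [11, 44]
  keyword_broad:
    inclusion: "polycystic_ovaries | hirsutism | irregular_menses"
    exclusion: pcos_exclusions
    keyword:
      required: true
      keywords: ["polycystic ovaries", "PCOS", "PCO"]
      note_types:
        - outpatient note
        - gynecology clinic visit
        - nursing report
        - endocrine and diabetes clinic visit
        - pediatric endocrinology patient visit
        - reproductive endocrinology clinic visit
    age_range: [11, 44]
  coded_broad:
    inclusion: "polycystic_ovaries | hirsutism | irregular_menses"
    exclusion: pcos_exclusions
    age_range: [11, 44]
  control:
    exclusion: pcos_exclusions
    age_range: [11, 44]
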