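# Synthetic code lists for the second-breast-cancer-event algorithm.
#
# These codes are invented stand-ins with ICD-like shape, used by the
# package's examples, tests and cohort generator.  They are NOT a
# clinically curated list and must be replaced with jurisdiction-specific
# curated lists before use on real data.
provenance: "Synthetic demonstration lists (non-clinical); shipped with the sbce package"
criteria:
  death_breast_cancer:
    sources: [cause_of_death]
    codes:
      code_system: ICD10-SYN
      match_mode: prefix
      codes:
        - C50
  procedure_diagnosis:
    sources: [inpatient_procedure, ambulatory_procedure]
    procedure_codes:
      code_system: CCI-SYN
      match_mode: prefix
      codes:
        - 1YM87   # partial excision, breast (lumpectomy-like)
        - 1YM89   # radical excision, breast (mastectomy-like)
        - 1YM91   # excision with lymph node dissection
    diagnosis_codes:
      code_system: ICD10-SYN
      match_mode: prefix
      codes:
        - C50     # malignant neoplasm of breast
        - C773    # secondary neoplasm, axillary nodes
        - C79     # secondary malignant neoplasm, distant site
  systemic_treatment:
    sources: [systemic_therapy]
    codes:
      code_system: DRUG-SYN
      match_mode: exact
      codes:
        - SYS001  # anthracycline-like cytotoxic
        - SYS002  # taxane-like cytotoxic
        - SYS003  # platinum-like cytotoxic
        - SYS004  # anti-HER2 biologic
        - SYS005  # CDK-inhibitor-like targeted agent
  radiotherapy:
    sources: [radiotherapy]
    codes:
      code_system: RT-SYN
      match_mode: exact
      codes:
        - RTBRST  # breast / chest wall irradiation
        - RTNODE  # regional nodal irradiation
        - RTMETA  # palliative irradiation of metastatic site
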