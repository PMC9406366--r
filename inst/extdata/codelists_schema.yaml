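# Machine-readable schema for sbce code-list files.
#
# A code-list file is a YAML document with two top-level keys:
#   provenance: free text describing where the lists came from
#   criteria:   a map that must contain exactly these four keys:
#               death_breast_cancer, procedure_diagnosis,
#               systemic_treatment, radiotherapy
#
# Every criterion block has:
#   sources: list drawn from {inpatient_procedure, ambulatory_procedure,
#            systemic_therapy, radiotherapy, cause_of_death}
#
# The procedure_diagnosis criterion has two code-set blocks
# (procedure_codes, diagnosis_codes); it matches an event only when the
# event's procedure code AND its associated diagnosis code both match.
# Every other criterion has a single `codes` block, either one pooled
# code set or a map from source name to code set.
#
# A code-set block:
#   code_system: string label; events from a different system never match
#   match_mode:  "exact" (default) or "prefix"
#   codes:       list of code strings, one per line; normalized to upper
#                case and trimmed on load; duplicates dropped with a
#                warning; in prefix mode no code may be a prefix of
#                another code in the same set (rejected on load)
schema_version: 1
top_level:
  provenance: {type: string, required: false}
  criteria:
    type: map
    required: true
    required_keys:
      - death_breast_cancer
      - procedure_diagnosis
      - systemic_treatment
      - radiotherapy
criterion_block:
  sources:
    type: list of enum
    values: [inpatient_procedure, ambulatory_procedure, systemic_therapy,
             radiotherapy, cause_of_death]
  codes: {type: code_set or map source -> code_set}
  procedure_codes: {type: code_set, only_for: procedure_diagnosis}
  diagnosis_codes: {type: code_set, only_for: procedure_diagnosis}
code_set:
  code_system: {type: string, required: true}
  match_mode: {type: enum, values: [exact, prefix], default: exact}
  codes: {type: list of string, required: true, min_length: 1}
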