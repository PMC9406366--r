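`%||%` <- function(x, y) if (is.null(x)) y else x

# cached package code lists
test_codelists <- local({
  cl <- NULL
  function() {
    if (is.null(cl)) cl <<- read_codelists(sbce_example_codelists())
    cl
  }
})

make_patient <- function(patient_id, diagnosis_date = "2010-01-01",
                         stage = "II", laterality = "left",
                         sex = "female", age_at_diagnosis = 60L,
                         death_date = NA, cause_of_death_code = NA_character_,
                         prior_breast_cancer = FALSE,
                         prior_other_cancer = FALSE,
                         histology_exclusion_flag = FALSE) {
  tibble::tibble(
    patient_id = patient_id,
    diagnosis_date = as.Date(diagnosis_date),
    stage = stage, laterality = laterality, sex = sex,
    age_at_diagnosis = as.integer(age_at_diagnosis),
    death_date = as.Date(death_date),
    cause_of_death_code = cause_of_death_code,
    prior_breast_cancer = prior_breast_cancer,
    prior_other_cancer = prior_other_cancer,
    histology_exclusion_flag = histology_exclusion_flag)
}

make_event <- function(patient_id, event_date, source, code,
                       code_system = "CCI-SYN",
                       diagnosis_code = NA_character_,
                       laterality = "unknown") {
  tibble::tibble(
    patient_id = patient_id, event_date = as.Date(event_date),
    source = source, code_system = code_system, code = code,
    diagnosis_code = diagnosis_code, laterality = laterality)
}

empty_events <- function() make_event(character(0), as.Date(character(0)),
                                      character(0), character(0),
                                      character(0), character(0),
                                      character(0))

# base R list used to write code-list YAML variants in tests
base_codelist_spec <- function() {
  list(
    provenance = "test",
    criteria = list(
      death_breast_cancer = list(
        sources = list("cause_of_death"),
        codes = list(code_system = "ICD10-SYN", match_mode = "prefix",
                     codes = list("C50"))),
      procedure_diagnosis = list(
        sources = list("inpatient_procedure", "ambulatory_procedure"),
        procedure_codes = list(code_system = "CCI-SYN",
                               match_mode = "prefix",
                               codes = list("1YM87")),
        diagnosis_codes = list(code_system = "ICD10-SYN",
                               match_mode = "prefix",
                               codes = list("C50"))),
      systemic_treatment = list(
        sources = list("systemic_therapy"),
        codes = list(code_system = "DRUG-SYN", match_mode = "exact",
                     codes = list("SYS001"))),
      radiotherapy = list(
        sources = list("radiotherapy"),
        codes = list(code_system = "RT-SYN", match_mode = "exact",
                     codes = list("RTBRST")))))
}

write_codelist_yaml <- function(spec, path = withr::local_tempfile(
                                  fileext = ".yaml",
                                  .local_envir = parent.frame())) {
  yaml::write_yaml(spec, path)
  path
}

# ---------------------------------------------------------------------
# Independent classification oracle: a plain-loop scan of the tables
# that re-derives per-patient classifications and per-criterion tallies
# straight from the code-list YAML, sharing no code with the package's
# dplyr pipeline.
oracle_classify <- function(patients, events, study_end,
                            washout = 180,
                            yaml_path = sbce_example_codelists()) {
  y <- yaml::read_yaml(yaml_path)
  set_match <- function(code, set) {
    if (is.na(code)) return(FALSE)
    code <- toupper(trimws(code))
    codes <- toupper(unlist(set$codes))
    if (identical(set$match_mode %||% "exact", "prefix")) {
      for (cc in codes) if (startsWith(code, cc)) return(TRUE)
      return(FALSE)
    }
    code %in% codes
  }
  study_end <- as.Date(study_end)
  crits <- c("death_breast_cancer", "procedure_diagnosis",
             "systemic_treatment", "radiotherapy")
  tally_events <- setNames(numeric(4), crits)
  tally_patients <- setNames(vector("list", 4), crits)
  tally_contra <- setNames(numeric(4), crits)

  out <- data.frame(patient_id = patients$patient_id,
                    is_sbce = FALSE, criteria_met = "",
                    first_event_date = as.Date(NA),
                    contralateral = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    ws <- p$diagnosis_date + washout
    we <- min(c(p$death_date, study_end), na.rm = TRUE)
    ev <- events[events$patient_id == p$patient_id, , drop = FALSE]
    if (!is.na(p$death_date) && !is.na(p$cause_of_death_code)) {
      ev <- rbind(ev, data.frame(
        patient_id = p$patient_id, event_date = p$death_date,
        source = "cause_of_death", code_system = NA_character_,
        code = p$cause_of_death_code, diagnosis_code = NA_character_,
        laterality = "unknown"))
    }
    key <- paste(ev$event_date, ev$source, ev$code, ev$diagnosis_code)
    ev <- ev[!duplicated(key), , drop = FALSE]
    met <- character(0)
    dates <- as.Date(character(0))
    contra <- FALSE
    for (j in seq_len(nrow(ev))) {
      e <- ev[j, ]
      if (!(e$event_date > ws && e$event_date <= we)) next
      hits <- character(0)
      if (e$source == "cause_of_death" &&
          set_match(e$code, y$criteria$death_breast_cancer$codes)) {
        hits <- c(hits, "death_breast_cancer")
      }
      if (e$source %in% c("inpatient_procedure", "ambulatory_procedure") &&
          set_match(e$code, y$criteria$procedure_diagnosis$procedure_codes) &&
          set_match(e$diagnosis_code,
                    y$criteria$procedure_diagnosis$diagnosis_codes)) {
        hits <- c(hits, "procedure_diagnosis")
      }
      if (e$source == "systemic_therapy" &&
          set_match(e$code, y$criteria$systemic_treatment$codes)) {
        hits <- c(hits, "systemic_treatment")
      }
      if (e$source == "radiotherapy" &&
          set_match(e$code, y$criteria$radiotherapy$codes)) {
        hits <- c(hits, "radiotherapy")
      }
      if (!length(hits)) next
      met <- union(met, hits)
      dates <- c(dates, e$event_date)
      for (h in hits) {
        tally_events[h] <- tally_events[h] + 1
        tally_patients[[h]] <- union(tally_patients[[h]], p$patient_id)
      }
      lateralized <- intersect(hits,
                               c("procedure_diagnosis", "radiotherapy"))
      if (length(lateralized) &&
          p$laterality %in% c("left", "right") &&
          e$laterality %in% c("left", "right") &&
          e$laterality != p$laterality) {
        contra <- TRUE
        for (h in lateralized) tally_contra[h] <- tally_contra[h] + 1
      }
    }
    if (length(met)) {
      out$is_sbce[i] <- TRUE
      out$criteria_met[i] <- paste(sort(met), collapse = ";")
      out$first_event_date[i] <- min(dates)
      out$contralateral[i] <- contra
    }
  }
  list(classifications = out,
       n_events = tally_events,
       n_patients = lengths(tally_patients),
       n_contralateral_events = tally_contra)
}

# independent eligibility oracle: plain row scan in the documented
# precedence order
oracle_exclusions <- function(patients, early_death_days = 180) {
  reasons <- character(nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    reasons[i] <-
      if (p$sex != "female") "non_female"
      else if (p$age_at_diagnosis < 18) "age_under_18"
      else if (!p$stage %in% c("0", "I", "II", "III")) "stage_out_of_range"
      else if (p$histology_exclusion_flag) "histology_exclusion"
      else if (!is.na(p$death_date) &&
               as.integer(p$death_date - p$diagnosis_date) <=
               early_death_days) "early_death"
      else "retained"
  }
  table(factor(reasons, levels = c("non_female", "age_under_18",
                                   "stage_out_of_range",
                                   "histology_exclusion", "early_death",
                                   "retained")))
}
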