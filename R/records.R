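#' Assemble a linked cohort from in-memory tables
#'
#' A linked cohort pairs one registry row per patient with the patient's
#' dated, coded healthcare-utilization events, censored at a common study
#' end date.  Events referencing an unknown patient (orphans) and events
#' dated after the patient's censoring date (the earlier of death and
#' `study_end`) are dropped with a message, matching how administrative
#' extracts are cleaned before analysis.
#'
#' @param patients Tibble with columns `patient_id`, `diagnosis_date`
#'   (Date), `stage` (`"0"`, `"I"`, `"II"`, `"III"`), `laterality`, `sex`,
#'   `age_at_diagnosis`, `death_date` (Date, `NA` if alive),
#'   `cause_of_death_code`, `prior_breast_cancer`, `prior_other_cancer`,
#'   `histology_exclusion_flag`.
#' @param events Tibble with columns `patient_id`, `event_date` (Date),
#'   `source` (one of the five utilization sources), `code_system`,
#'   `code`, `diagnosis_code` (`NA` for non-procedure events),
#'   `laterality`.
#' @param study_end Date; administrative end of follow-up.
#' @return An object of class `sbce_cohort`: a list with tibbles
#'   `patients` and `events`, the `study_end` date, and a `dropped`
#'   tally of removed event rows.
#' @export
sbce_cohort <- function(patients, events, study_end) {
  study_end <- as.Date(study_end)
  patients <- as_tibble(patients)
  events <- as_tibble(events)
  if (anyDuplicated(patients$patient_id)) {
    dup <- unique(patients$patient_id[duplicated(patients$patient_id)])
    abort(paste0("Duplicate patient_id in registry: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  bad_death <- !is.na(patients$death_date) &
    patients$death_date < patients$diagnosis_date
  if (any(bad_death)) {
    abort(paste0("death_date precedes diagnosis_date for patient(s): ",
                 paste(head(patients$patient_id[bad_death], 5),
                       collapse = ", ")))
  }

  n0 <- nrow(events)
  events <- semi_join(events, patients, by = "patient_id")
  n_orphan <- n0 - nrow(events)

  censor <- patients %>%
    mutate(censor_date = pmin(.data$death_date, study_end, na.rm = TRUE)) %>%
    select("patient_id", "censor_date")
  events <- events %>%
    left_join(censor, by = "patient_id") %>%
    filter(.data$event_date <= .data$censor_date) %>%
    select(-"censor_date")
  n_censored <- n0 - n_orphan - nrow(events)

  if (n_orphan + n_censored > 0) {
    inform(sprintf(
      "Dropped %d event row(s): %d orphan (unknown patient_id), %d after censoring.",
      n_orphan + n_censored, n_orphan, n_censored))
  }
  structure(
    list(patients = patients, events = events, study_end = study_end,
         dropped = c(orphan = n_orphan, post_censoring = n_censored)),
    class = "sbce_cohort")
}

registry_cols <- function() {
  c("patient_id", "diagnosis_date", "stage", "laterality", "sex",
    "age_at_diagnosis", "death_date", "cause_of_death_code",
    "prior_breast_cancer", "prior_other_cancer", "histology_exclusion_flag")
}

events_cols <- function() {
  c("patient_id", "event_date", "source", "code_system", "code",
    "diagnosis_code", "laterality")
}

parse_iso_date <- function(x) {
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

parse_flag <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO", "")] <- FALSE
  out[is.na(x)] <- FALSE
  out
}

blank_to_unknown <- function(x) {
  x <- tolower(trimws(x))
  x[is.na(x) | !nzchar(x)] <- "unknown"
  x
}

collect_row_errors <- function(df, checks, file) {
  purrr::map_dfr(names(checks), function(col) {
    bad <- which(checks[[col]])
    tibble(file = file, row = bad, column = col,
           value = as.character(df[[col]][bad]))
  })
}

#' Read a linked cohort from delimited text files
#'
#' Reads the registry and events tables (comma-delimited by default, tab
#' accepted via `delim`), validates them row by row, and assembles an
#' [sbce_cohort()].  Validation failures (unparseable dates, unknown
#' stage/source/laterality values) are reported with file and row
#' numbers; by default any failing row is fatal, while `skip_bad = TRUE`
#' drops failing rows with a warning instead.
#'
#' @param registry_path Path to the registry file (columns as in
#'   [sbce_cohort()]).
#' @param events_path Character vector of one or more event-file paths;
#'   multiple files are concatenated (e.g. inpatient and ambulatory
#'   extracts delivered separately).
#' @param study_end Date; end of follow-up (default `"2013-12-31"`).
#' @param delim Field delimiter; `","` default, `"\t"` accepted.
#' @param skip_bad Drop invalid rows instead of failing.
#' @return An `sbce_cohort`.
#' @export
read_cohort <- function(registry_path, events_path,
                        study_end = as.Date("2013-12-31"),
                        delim = ",", skip_bad = FALSE) {
  read_chr <- function(path) {
    readr::read_delim(path, delim = delim, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }

  reg <- read_chr(registry_path)
  miss <- setdiff(registry_cols(), names(reg))
  if (length(miss)) {
    abort(paste0("Registry file ", registry_path,
                 " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  reg_parsed <- reg %>%
    mutate(
      diagnosis_date = parse_iso_date(.data$diagnosis_date),
      death_date = parse_iso_date(.data$death_date),
      stage = trimws(.data$stage),
      laterality = blank_to_unknown(.data$laterality),
      sex = blank_to_unknown(.data$sex),
      age_at_diagnosis = suppressWarnings(as.integer(.data$age_at_diagnosis)),
      prior_breast_cancer = parse_flag(.data$prior_breast_cancer),
      prior_other_cancer = parse_flag(.data$prior_other_cancer),
      histology_exclusion_flag = parse_flag(.data$histology_exclusion_flag))
  reg_errors <- collect_row_errors(reg, list(
    diagnosis_date = is.na(reg_parsed$diagnosis_date),
    death_date = is.na(reg_parsed$death_date) & !is.na(reg$death_date) &
      nzchar(trimws(reg$death_date)),
    stage = !reg_parsed$stage %in% stage_levels(),
    laterality = !reg_parsed$laterality %in% laterality_levels(),
    age_at_diagnosis = is.na(reg_parsed$age_at_diagnosis)
  ), registry_path)

  evt <- purrr::map_dfr(events_path, read_chr)
  miss <- setdiff(events_cols(), names(evt))
  if (length(miss)) {
    abort(paste0("Events file(s) missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  evt_parsed <- evt %>%
    mutate(
      event_date = parse_iso_date(.data$event_date),
      source = trimws(.data$source),
      laterality = blank_to_unknown(.data$laterality))
  evt_errors <- collect_row_errors(evt, list(
    event_date = is.na(evt_parsed$event_date),
    source = !evt_parsed$source %in% event_sources(),
    laterality = !evt_parsed$laterality %in% laterality_levels()
  ), paste(events_path, collapse = ";"))

  errors <- bind_rows(reg_errors, evt_errors)
  if (nrow(errors)) {
    msg <- paste0(
      nrow(errors), " invalid row value(s), e.g. ",
      paste(sprintf("%s row %d [%s]: \"%s\"",
                    head(errors$file, 3), head(errors$row, 3),
                    head(errors$column, 3), head(errors$value, 3)),
            collapse = "; "))
    if (!skip_bad) abort(paste0(msg, ". Use skip_bad = TRUE to drop them."))
    warn(paste0(msg, ". Dropping affected rows."))
    drop_rows <- function(df, rows) {
      if (length(rows)) df[-unique(rows), , drop = FALSE] else df
    }
    reg_parsed <- drop_rows(reg_parsed, reg_errors$row)
    evt_parsed <- drop_rows(evt_parsed, evt_errors$row)
  }

  sbce_cohort(reg_parsed, evt_parsed, study_end)
}

exclusion_reasons <- function() {
  c("non_female", "age_under_18", "stage_out_of_range",
    "histology_exclusion", "early_death")
}

#' Apply cohort eligibility criteria
#'
#' Retains patients who are female, at least 18 at diagnosis, staged
#' 0–III, not carrying the registry's breast-lymphoma / breast-skin-cancer
#' exclusion flag, and alive more than 180 days after diagnosis (death on
#' day 180 or earlier excludes; survival to day 181 retains — the boundary
#' pairs with the algorithm's 180-day washout).  Patients with prior
#' cancer diagnoses are retained.  Events of excluded patients are
#' removed alongside them.
#'
#' Each excluded patient is assigned exactly one reason, the first match
#' in the fixed order non-female, age, stage, histology flag, early
#' death, so reason counts plus the retained count always sum to the
#' input count.  The operation is idempotent.
#'
#' @param cohort An [sbce_cohort()].
#' @param early_death_days Exclusion threshold in days (default 180).
#' @return The filtered `sbce_cohort`, with an `exclusions` tibble
#'   (`reason`, `n`, all reasons listed) added.
#' @export
filter_eligible <- function(cohort, early_death_days = 180) {
  stopifnot(inherits(cohort, "sbce_cohort"))
  p <- cohort$patients
  reason <- dplyr::case_when(
    p$sex != "female" ~ "non_female",
    p$age_at_diagnosis < 18 ~ "age_under_18",
    !p$stage %in% stage_levels() ~ "stage_out_of_range",
    p$histology_exclusion_flag ~ "histology_exclusion",
    !is.na(p$death_date) &
      as.integer(p$death_date - p$diagnosis_date) <= early_death_days ~
      "early_death",
    TRUE ~ NA_character_)
  tally <- tibble(reason = exclusion_reasons()) %>%
    left_join(tibble(reason = reason[!is.na(reason)]) %>% count(.data$reason),
              by = "reason") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  keep <- p[is.na(reason), , drop = FALSE]
  out <- sbce_cohort(keep,
                     semi_join(cohort$events, keep, by = "patient_id"),
                     cohort$study_end)
  out$exclusions <- tally
  out
}

#' @export
print.sbce_cohort <- function(x, ...) {
  cat(sprintf("<sbce_cohort> %d patients, %d events, study end %s\n",
              nrow(x$patients), nrow(x$events),
              format(x$study_end)))
  if (!is.null(x$exclusions)) {
    excl <- x$exclusions[x$exclusions$n > 0, , drop = FALSE]
    if (nrow(excl)) {
      cat("  exclusions:",
          paste(sprintf("%s=%d", excl$reason, excl$n), collapse = ", "),
          "\n")
    } else {
      cat("  exclusions: none\n")
    }
  }
  invisible(x)
}
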