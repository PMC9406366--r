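#' Per-patient observation windows
#'
#' The algorithm scans each patient's utilization from 180 days
#' post-diagnosis (the washout boundary) to death or the administrative
#' end of follow-up, whichever comes first.  Events inside the washout
#' are attributed to primary treatment and never qualify; an event dated
#' exactly `washout_days` after diagnosis is still washout — a qualifying
#' event must be *more than* `washout_days` after diagnosis.
#'
#' @param patients Registry tibble (as in [sbce_cohort()]).
#' @param washout_days Washout length in whole days (default 180).
#' @param study_end Date; end of follow-up.
#' @return Tibble `patient_id`, `window_start`, `window_end`.  Events
#'   qualify when `window_start < event_date <= window_end`; a window
#'   with `window_start >= window_end` is empty.
#' @export
observation_window <- function(patients, washout_days = 180, study_end) {
  stopifnot(washout_days >= 0)
  study_end <- as.Date(study_end)
  patients %>%
    mutate(
      window_start = .data$diagnosis_date + washout_days,
      window_end = pmin(.data$death_date, study_end, na.rm = TRUE)) %>%
    select("patient_id", "window_start", "window_end")
}

# Deduplicate utilization rows: administrative extracts routinely repeat
# the same record across feeds.  Identity = (patient, date, source, code,
# associated diagnosis); the first row's laterality is kept.
dedup_events <- function(events) {
  events %>%
    dplyr::distinct(.data$patient_id, .data$event_date, .data$source,
                    .data$code, .data$diagnosis_code, .keep_all = TRUE)
}

# The death criterion reads the registry's vital-status fields; it is
# materialized as pseudo-events so all four criteria share one matching
# path.  Explicit cause_of_death rows in the events table (if a feed
# supplies them) travel the same path and collapse under deduplication.
death_pseudo_events <- function(patients) {
  patients %>%
    filter(!is.na(.data$death_date), !is.na(.data$cause_of_death_code),
           nzchar(.data$cause_of_death_code)) %>%
    mutate(event_date = .data$death_date,
           source = "cause_of_death",
           code_system = NA_character_,
           code = .data$cause_of_death_code,
           diagnosis_code = NA_character_,
           laterality = "unknown") %>%
    select(dplyr::all_of(events_cols()))
}

match_criterion_events <- function(events, criterion) {
  ev <- events %>% filter(.data$source %in% criterion$sources)
  if (nrow(ev) == 0L) return(ev)
  hit <- if (criterion$criterion_id == "procedure_diagnosis") {
    # conjunction: the same event must carry a matching procedure code
    # AND a matching associated diagnosis code
    match_code(ev$code, criterion$code_sets$procedure) &
      !is.na(ev$diagnosis_code) &
      match_code(ev$diagnosis_code, criterion$code_sets$diagnosis)
  } else if (!is.null(criterion$code_sets$pooled)) {
    match_code(ev$code, criterion$code_sets$pooled)
  } else {
    out <- rep(FALSE, nrow(ev))
    for (src in names(criterion$code_sets)) {
      sel <- ev$source == src
      out[sel] <- match_code(ev$code[sel], criterion$code_sets[[src]])
    }
    out
  }
  ev[hit, , drop = FALSE]
}

#' Evaluate one algorithm criterion over a cohort
#'
#' Returns the deduplicated events that satisfy the criterion inside each
#' patient's observation window.  The `death_breast_cancer` criterion is
#' evaluated from the registry's death date and cause-of-death code,
#' treated as a pseudo-event dated at death.
#'
#' @param cohort An eligible [sbce_cohort()].
#' @param codelists An [read_codelists()] registry.
#' @param criterion_id One of `"death_breast_cancer"`,
#'   `"procedure_diagnosis"`, `"systemic_treatment"`, `"radiotherapy"`.
#' @param washout_days Washout length in days (default 180).
#' @return Tibble of qualifying events with a `criterion` column.
#' @export
evaluate_criterion <- function(cohort, codelists, criterion_id,
                               washout_days = 180) {
  stopifnot(inherits(cohort, "sbce_cohort"),
            inherits(codelists, "sbce_codelists"))
  criterion_id <- match.arg(criterion_id, criterion_ids())
  criterion <- codelists$criteria[[criterion_id]]

  pool <- bind_rows(cohort$events, death_pseudo_events(cohort$patients)) %>%
    dedup_events()
  win <- observation_window(cohort$patients, washout_days, cohort$study_end)
  match_criterion_events(pool, criterion) %>%
    inner_join(win, by = "patient_id") %>%
    filter(.data$event_date > .data$window_start,
           .data$event_date <= .data$window_end) %>%
    select(-"window_start", -"window_end") %>%
    mutate(criterion = criterion_id)
}

#' Flag probable contralateral second primaries
#'
#' Among patients with a qualifying event, a probable contralateral
#' second primary is flagged when the original cancer has a definite side
#' (left or right) and at least one qualifying event from a lateralized
#' criterion (procedures, radiotherapy) is on the strictly opposite side.
#' Bilateral or unknown laterality on either side never triggers the
#' flag; the call is deliberately conservative.
#'
#' @param patients Registry tibble.
#' @param qualifying_events Tibble of qualifying events with a
#'   `criterion` column (as from [evaluate_criterion()]).
#' @return Tibble `patient_id`, `contralateral` (one row per patient in
#'   `patients`).
#' @export
flag_contralateral <- function(patients, qualifying_events) {
  opposite <- c(left = "right", right = "left")
  sided <- patients %>%
    filter(.data$laterality %in% c("left", "right")) %>%
    select("patient_id", patient_side = "laterality")
  flags <- qualifying_events %>%
    filter(.data$criterion %in% laterality_capable_criteria()) %>%
    inner_join(sided, by = "patient_id") %>%
    filter(.data$laterality == opposite[.data$patient_side]) %>%
    dplyr::distinct(.data$patient_id) %>%
    mutate(contralateral = TRUE)
  patients %>%
    select("patient_id") %>%
    left_join(flags, by = "patient_id") %>%
    mutate(contralateral = tidyr::replace_na(.data$contralateral, FALSE))
}

#' Classify a single patient
#'
#' Convenience wrapper around the cohort path for one patient: a patient
#' is classified as having a second breast cancer event on meeting any
#' one of the four criteria a single time inside the observation window.
#' Criteria are independent, so evaluation order cannot change the
#' result.
#'
#' @param patient One-row registry tibble.
#' @param events The patient's events tibble (may be empty).
#' @param codelists An [read_codelists()] registry.
#' @param washout_days Washout length in days.
#' @param study_end End of follow-up.
#' @return One-row tibble: `patient_id`, `is_sbce`, `criteria_met`
#'   (semicolon-joined), `first_event_date`, `contralateral`.
#' @export
classify_patient <- function(patient, events, codelists,
                             washout_days = 180, study_end) {
  stopifnot(nrow(patient) == 1L)
  cohort <- sbce_cohort(patient, events, study_end)
  res <- classify_cohort(cohort, codelists, washout_days)
  res$classifications
}

#' Apply the SBCE algorithm to an eligible cohort
#'
#' Evaluates the four criteria over every patient and aggregates the
#' results: per-patient classifications, per-criterion patient / event /
#' contralateral-event tallies, the mutually exclusive
#' criterion-combination partition (each SBCE patient falls in exactly
#' one combination cell), per-stage rates, and the overall SBCE rate.
#'
#' @param cohort An eligible [sbce_cohort()].
#' @param codelists An [read_codelists()] registry.
#' @param washout_days Washout length in days (default 180).
#' @return An object of class `sbce_classification` with elements
#'   `classifications`, `qualifying_events`, `criterion_tally`,
#'   `combination_tally`, `per_stage`, `sbce_rate`, `n_patients`.
#'   [generics::tidy()] returns the per-patient table,
#'   [generics::glance()] a one-row cohort summary, and
#'   [ggplot2::autoplot()] the criterion-combination bar chart.
#' @examples
#' cl <- read_codelists(sbce_example_codelists())
#' sim <- generate_cohort(simulation_config(n_patients = 200, seed = 1))
#' classify_cohort(sim$cohort, cl)
#' @export
classify_cohort <- function(cohort, codelists, washout_days = 180) {
  stopifnot(inherits(cohort, "sbce_cohort"))
  qual <- purrr::map_dfr(
    criterion_ids(),
    function(cid) evaluate_criterion(cohort, codelists, cid, washout_days))

  patients <- cohort$patients
  contra <- flag_contralateral(patients, qual)

  per_patient <- if (nrow(qual) == 0L) {
    tibble(patient_id = character(0), criteria_met = character(0),
           first_event_date = as.Date(character(0)))
  } else {
    qual %>%
      group_by(.data$patient_id) %>%
      summarise(
        criteria_met = paste(sort(unique(.data$criterion)),
                             collapse = ";"),
        first_event_date = min(.data$event_date),
        .groups = "drop")
  }
  classifications <- patients %>%
    select("patient_id", "stage") %>%
    left_join(per_patient, by = "patient_id") %>%
    left_join(contra, by = "patient_id") %>%
    mutate(
      is_sbce = !is.na(.data$criteria_met),
      criteria_met = tidyr::replace_na(.data$criteria_met, "")) %>%
    select("patient_id", "stage", "is_sbce", "criteria_met",
           "first_event_date", "contralateral")

  opposite <- c(left = "right", right = "left")
  contra_evt <- qual %>%
    left_join(patients %>%
                select("patient_id", patient_side = "laterality"),
              by = "patient_id") %>%
    mutate(is_contra = .data$criterion %in% laterality_capable_criteria() &
             .data$patient_side %in% c("left", "right") &
             .data$laterality == unname(opposite[.data$patient_side]) &
             !is.na(.data$laterality))

  criterion_tally <- tibble(criterion = criterion_ids()) %>%
    left_join(
      contra_evt %>%
        group_by(.data$criterion) %>%
        summarise(n_patients = dplyr::n_distinct(.data$patient_id),
                  n_events = n(),
                  n_contralateral_events =
                    sum(.data$is_contra, na.rm = TRUE),
                  .groups = "drop"),
      by = "criterion") %>%
    mutate(across(c("n_patients", "n_events", "n_contralateral_events"),
                  ~ tidyr::replace_na(.x, 0L)),
           n_contralateral_events = if_else(
             .data$criterion %in% laterality_capable_criteria(),
             .data$n_contralateral_events, NA_integer_))

  combination_tally <- classifications %>%
    filter(.data$is_sbce) %>%
    count(combination = .data$criteria_met, name = "n_patients") %>%
    arrange(dplyr::desc(.data$n_patients))

  per_stage <- patients %>%
    select("patient_id", "stage") %>%
    left_join(classifications %>% select("patient_id", "is_sbce"),
              by = "patient_id") %>%
    group_by(.data$stage) %>%
    summarise(n = n(), n_sbce = sum(.data$is_sbce),
              sbce_rate = .data$n_sbce / .data$n, .groups = "drop")

  structure(
    list(classifications = classifications,
         qualifying_events = qual,
         criterion_tally = criterion_tally,
         combination_tally = combination_tally,
         per_stage = per_stage,
         n_patients = nrow(patients),
         sbce_rate = mean(classifications$is_sbce)),
    class = "sbce_classification")
}

#' @export
print.sbce_classification <- function(x, ...) {
  cat(sprintf(
    "<sbce_classification> %d patients, %d with an SBCE (%.1f%%), %d probable contralateral\n",
    x$n_patients, sum(x$classifications$is_sbce), 100 * x$sbce_rate,
    sum(x$classifications$contralateral)))
  print(x$criterion_tally)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy sbce_classification
#' @export
tidy.sbce_classification <- function(x, ...) x$classifications

#' @method glance sbce_classification
#' @export
glance.sbce_classification <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    n_sbce = sum(x$classifications$is_sbce),
    sbce_rate = x$sbce_rate,
    n_contralateral = sum(x$classifications$contralateral),
    n_qualifying_events = nrow(x$qualifying_events))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of the criterion-combination partition
#'
#' Mirrors the standard presentation of rule-based phenotyping output:
#' SBCE patients partitioned by the exact combination of criteria met
#' (single-criterion groups vs combinations), mutually exclusive and
#' collectively exhaustive.
#'
#' @param object An `sbce_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sbce_classification
#' @export
autoplot.sbce_classification <- function(object, ...) {
  df <- object$combination_tally %>%
    mutate(
      single = !grepl(";", .data$combination),
      combination = stats::reorder(.data$combination, .data$n_patients))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$combination,
                                   y = .data$n_patients,
                                   fill = .data$single)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "grey35", `FALSE` = "steelblue"),
      labels = c(`TRUE` = "single criterion", `FALSE` = "combination"),
      name = NULL) +
    ggplot2::labs(x = "criteria met", y = "patients",
                  title = "SBCE patients by criterion combination")
}

#' Write the per-patient classification table
#'
#' @param x An `sbce_classification`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(x, path) {
  stopifnot(inherits(x, "sbce_classification"))
  readr::write_csv(x$classifications, path)
  invisible(path)
}

#' Cohort summary table, optionally with small-cell suppression
#'
#' Formats the per-criterion tallies the way published summaries of this
#' kind of algorithm present them.  With `suppress_small_cells = TRUE`,
#' counts of 1–5 are rendered `"<6"`, the usual privacy convention for
#' published administrative-data tables; the underlying object is never
#' altered.
#'
#' @param x An `sbce_classification`.
#' @param suppress_small_cells Render counts 1–5 as `"<6"`.
#' @return A tibble of formatted counts.
#' @export
cohort_summary <- function(x, suppress_small_cells = FALSE) {
  stopifnot(inherits(x, "sbce_classification"))
  fmt <- function(n) {
    if (suppress_small_cells) {
      if_else(!is.na(n) & n >= 1 & n <= 5, "<6", as.character(n))
    } else {
      as.character(n)
    }
  }
  x$criterion_tally %>%
    mutate(across(c("n_patients", "n_events", "n_contralateral_events"),
                  fmt)) %>%
    bind_rows(tibble(
      criterion = "any_criterion",
      n_patients = fmt(sum(x$classifications$is_sbce)),
      n_events = fmt(nrow(x$qualifying_events)),
      n_contralateral_events =
        fmt(sum(x$classifications$contralateral))))
}
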