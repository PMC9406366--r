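#' Configuration for the synthetic administrative cohort generator
#'
#' The generator emulates the joint structure of a cancer registry linked
#' to utilization feeds: stage-dependent second-event risk, dated coded
#' events from several sources with laterality, primary-treatment events
#' inside the washout window, false-positive-generating events after it
#' (e.g. delayed reconstruction surgery), truly unobservable second
#' events (endocrine-only or palliative management that leaves no
#' criterion-matching trace), and an imperfect manual-review reference
#' standard.
#'
#' Defaults describe a population-registry cohort followed for roughly
#' one to five years: the stage mix of an incident early-breast-cancer
#' population; per-stage true second-event probabilities of 4% / 2% /
#' 7.7% / 20% for stages 0 / I / II / III; and review error rates small
#' relative to the event rate.
#'
#' @param n_patients Number of patients.
#' @param stage_distribution Named proportions over stages 0, I, II, III
#'   (must sum to 1).
#' @param sbce_prob Named per-stage probability of a true second breast
#'   cancer event during follow-up.
#' @param diagnosis_window Two dates; diagnosis dates are uniform within.
#' @param study_end Administrative end of follow-up; must leave more
#'   than `washout_days` of follow-up after the latest diagnosis date.
#' @param washout_days Washout length in days (default 180).
#' @param detectability Named per-criterion probability that a true,
#'   visible second event emits at least one qualifying event of that
#'   criterion.
#' @param invisible_treatment_prob Probability a true second event emits
#'   no qualifying events at all.
#' @param false_positive_event_rate Probability a patient without a true
#'   second event emits one criterion-matching event after the washout.
#' @param contralateral_prob Probability a true second event (in a
#'   patient with known laterality) is contralateral.
#' @param review_miss_prob,review_false_call_prob Error rates of the
#'   simulated manual review on true positives / true negatives.
#' @param primary_treatment_event_prob Probability a patient has
#'   criterion-matching primary-treatment events inside the washout.
#' @param seed Integer master seed; one seed drives three independent
#'   substreams (patients and truth; events; review) so changing review
#'   noise leaves the cohort untouched.
#' @return A validated list of class `sbce_sim_config`.
#' @export
simulation_config <- function(
    n_patients = 2000,
    stage_distribution = c("0" = 0.048, "I" = 0.427, "II" = 0.382,
                           "III" = 0.143),
    sbce_prob = c("0" = 0.04, "I" = 0.02, "II" = 0.077, "III" = 0.20),
    diagnosis_window = as.Date(c("2009-01-01", "2012-12-31")),
    study_end = as.Date("2013-12-31"),
    washout_days = 180,
    detectability = c(death_breast_cancer = 0.05,
                      procedure_diagnosis = 0.65,
                      systemic_treatment = 0.35,
                      radiotherapy = 0.40),
    invisible_treatment_prob = 0.10,
    false_positive_event_rate = 0.06,
    contralateral_prob = 0.10,
    review_miss_prob = 0.05,
    review_false_call_prob = 0.01,
    primary_treatment_event_prob = 0.80,
    seed = 1L) {
  probs <- c(sbce_prob, detectability, invisible_treatment_prob,
             false_positive_event_rate, contralateral_prob,
             review_miss_prob, review_false_call_prob,
             primary_treatment_event_prob, stage_distribution)
  if (any(probs < 0 | probs > 1)) {
    abort("All simulation probabilities must lie in [0, 1].")
  }
  if (abs(sum(stage_distribution) - 1) > 1e-8) {
    abort("stage_distribution must sum to 1.")
  }
  miss <- setdiff(stage_levels(), names(stage_distribution))
  if (length(miss)) abort("stage_distribution must name all four stages.")
  if (length(setdiff(criterion_ids(), names(detectability)))) {
    abort("detectability must name all four criteria.")
  }
  diagnosis_window <- as.Date(diagnosis_window)
  study_end <- as.Date(study_end)
  if (as.integer(study_end - diagnosis_window[2]) <= washout_days) {
    abort("study_end must leave more than washout_days of follow-up after the latest diagnosis date.")
  }
  if (n_patients < 1) abort("n_patients must be >= 1.")
  structure(
    list(n_patients = as.integer(n_patients),
         stage_distribution = stage_distribution[stage_levels()],
         sbce_prob = sbce_prob[stage_levels()],
         diagnosis_window = diagnosis_window, study_end = study_end,
         washout_days = washout_days,
         detectability = detectability[criterion_ids()],
         invisible_treatment_prob = invisible_treatment_prob,
         false_positive_event_rate = false_positive_event_rate,
         contralateral_prob = contralateral_prob,
         review_miss_prob = review_miss_prob,
         review_false_call_prob = review_false_call_prob,
         primary_treatment_event_prob = primary_treatment_event_prob,
         seed = as.integer(seed)),
    class = "sbce_sim_config")
}

# One master seed, three reproducible substreams.
substream_seeds <- function(config) {
  withr::with_seed(config$seed,
                   setNames(sample.int(.Machine$integer.max - 1L, 3),
                            c("patients", "events", "review")))
}

# integer-uniform draw on [lo, hi], vectorized over lo/hi
draw_offsets <- function(n, lo, hi) {
  lo + floor(runif(n) * (hi - lo + 1))
}

sample_codes <- function(code_set, n) {
  sample(code_set$codes, n, replace = TRUE)
}

event_row_template <- function(patient_id, offset, diagnosis_date, source,
                               code_system, code, diagnosis_code,
                               laterality) {
  tibble(patient_id = patient_id,
         event_date = diagnosis_date + offset,
         source = source, code_system = code_system, code = code,
         diagnosis_code = diagnosis_code, laterality = laterality)
}

#' Generate a synthetic linked cohort with known ground truth
#'
#' Draws patients (stage, diagnosis date, laterality), plants true second
#' breast cancer events per the stage-specific probabilities, and emits
#' the corresponding utilization records: qualifying events per criterion
#' detectability for visible true events, primary-treatment events inside
#' the washout for most patients, and occasional criterion-matching
#' false-positive events for patients without a true second event.  All
#' codes are drawn from the packaged synthetic code lists, so the
#' classification engine resolves every generated event.  Fully
#' deterministic given the config seed.
#'
#' When the death criterion fires for a true second event, the patient's
#' death date is placed at or after all of that patient's other planted
#' events (and at or before `study_end`), so no planted event is lost to
#' censoring and the probability that a true event emits at least one
#' qualifying event is exactly
#' `(1 - invisible_treatment_prob) * (1 - prod(1 - detectability))`.
#'
#' @param config A [simulation_config()].
#' @param codelists Code lists used to draw event codes (defaults to the
#'   packaged synthetic lists).
#' @return A list with `cohort` (an [sbce_cohort()]) and `truth` (tibble
#'   `patient_id`, `true_sbce`, `true_sbce_date`, `contralateral_truth`).
#' @export
generate_cohort <- function(config,
                            codelists = read_codelists(
                              sbce_example_codelists())) {
  stopifnot(inherits(config, "sbce_sim_config"))
  ss <- substream_seeds(config)
  n <- config$n_patients
  washout <- config$washout_days
  span <- as.integer(config$diagnosis_window[2] -
                       config$diagnosis_window[1])

  # --- substream 1: patients and ground truth -------------------------
  pt <- withr::with_seed(ss[["patients"]], {
    stage <- sample(stage_levels(), n, replace = TRUE,
                    prob = config$stage_distribution)
    diagnosis_date <- config$diagnosis_window[1] + draw_offsets(n, 0, span)
    laterality <- sample(c("left", "right", "unknown"), n, replace = TRUE,
                         prob = c(0.49, 0.49, 0.02))
    age <- pmin(95L, pmax(18L, as.integer(round(rnorm(n, 61, 13)))))
    gap <- as.integer(config$study_end - diagnosis_date)
    true_sbce <- rbinom(n, 1, unname(config$sbce_prob[stage])) == 1
    sbce_offset <- ifelse(
      true_sbce, draw_offsets(n, washout + 1, gap), NA_integer_)
    contra_truth <- true_sbce & laterality %in% c("left", "right") &
      rbinom(n, 1, config$contralateral_prob) == 1
    tibble(
      patient_id = sprintf("P%06d", seq_len(n)),
      diagnosis_date = diagnosis_date, stage = stage,
      laterality = laterality, sex = "female", age_at_diagnosis = age,
      prior_breast_cancer = rbinom(n, 1, 0.04) == 1,
      prior_other_cancer = rbinom(n, 1, 0.055) == 1,
      histology_exclusion_flag = FALSE,
      gap = gap, true_sbce = true_sbce,
      sbce_offset = as.integer(sbce_offset),
      contra_truth = contra_truth)
  })

  cl <- codelists$criteria
  # event-side laterality: contralateral truths flip the planted side
  opposite <- c(left = "right", right = "left")
  evt_side <- ifelse(
    pt$laterality %in% c("left", "right"),
    ifelse(pt$contra_truth, opposite[pt$laterality], pt$laterality),
    "unknown")

  # --- substream 2: utilization events --------------------------------
  gen <- withr::with_seed(ss[["events"]], {
    visible <- pt$true_sbce &
      rbinom(n, 1, config$invisible_treatment_prob) == 0
    active <- sapply(criterion_ids(), function(cid) {
      visible & rbinom(n, 1, config$detectability[[cid]]) == 1
    })

    expand_events <- function(sel, n_extra_prob, build) {
      n_ev <- ifelse(sel, 1L + rbinom(n, 1, n_extra_prob), 0L)
      idx <- rep(seq_len(n), n_ev)
      if (!length(idx)) return(NULL)
      offs <- draw_offsets(length(idx), pt$sbce_offset[idx], pt$gap[idx])
      build(idx, offs)
    }

    proc_ev <- expand_events(active[, "procedure_diagnosis"], 0.3,
      function(idx, offs) {
        event_row_template(
          pt$patient_id[idx], offs, pt$diagnosis_date[idx],
          sample(c("inpatient_procedure", "ambulatory_procedure"),
                 length(idx), replace = TRUE),
          cl$procedure_diagnosis$code_sets$procedure$code_system,
          sample_codes(cl$procedure_diagnosis$code_sets$procedure,
                       length(idx)),
          sample_codes(cl$procedure_diagnosis$code_sets$diagnosis,
                       length(idx)),
          evt_side[idx])
      })
    sys_ev <- expand_events(active[, "systemic_treatment"], 0.3,
      function(idx, offs) {
        event_row_template(
          pt$patient_id[idx], offs, pt$diagnosis_date[idx],
          "systemic_therapy",
          cl$systemic_treatment$code_sets$pooled$code_system,
          sample_codes(cl$systemic_treatment$code_sets$pooled,
                       length(idx)),
          NA_character_, "unknown")
      })
    rt_ev <- expand_events(active[, "radiotherapy"], 0.3,
      function(idx, offs) {
        event_row_template(
          pt$patient_id[idx], offs, pt$diagnosis_date[idx],
          "radiotherapy",
          cl$radiotherapy$code_sets$pooled$code_system,
          sample_codes(cl$radiotherapy$code_sets$pooled, length(idx)),
          NA_character_, evt_side[idx])
      })

    sbce_events <- bind_rows(proc_ev, sys_ev, rt_ev)

    # death-from-breast-cancer criterion: place the death at or after
    # every other planted event so censoring never swallows one
    death_sel <- which(active[, "death_breast_cancer"])
    death <- tibble(patient_id = character(), death_offset = integer(),
                    cause = character())
    if (length(death_sel)) {
      latest <- sbce_events %>%
        mutate(offset = as.integer(.data$event_date -
                                     pt$diagnosis_date[
                                       match(.data$patient_id,
                                             pt$patient_id)])) %>%
        group_by(.data$patient_id) %>%
        summarise(latest = max(.data$offset), .groups = "drop")
      lo <- pmax(pt$sbce_offset[death_sel],
                 latest$latest[match(pt$patient_id[death_sel],
                                     latest$patient_id)],
                 na.rm = TRUE)
      death <- tibble(
        patient_id = pt$patient_id[death_sel],
        death_offset = draw_offsets(length(death_sel), lo,
                                    pt$gap[death_sel]),
        cause = sample(c("C500", "C504", "C509"), length(death_sel),
                       replace = TRUE))
    }

    # criterion-matching false positives for patients without a true
    # second event (delayed reconstruction and the like)
    fp_sel <- !pt$true_sbce &
      rbinom(n, 1, config$false_positive_event_rate) == 1
    fp_ev <- if (any(fp_sel)) {
      idx <- which(fp_sel)
      offs <- draw_offsets(length(idx), washout + 1, pt$gap[idx])
      event_row_template(
        pt$patient_id[idx], offs, pt$diagnosis_date[idx],
        sample(c("inpatient_procedure", "ambulatory_procedure"),
               length(idx), replace = TRUE),
        cl$procedure_diagnosis$code_sets$procedure$code_system,
        sample_codes(cl$procedure_diagnosis$code_sets$procedure,
                     length(idx)),
        sample_codes(cl$procedure_diagnosis$code_sets$diagnosis,
                     length(idx)),
        ifelse(pt$laterality[idx] %in% c("left", "right"),
               pt$laterality[idx], "unknown"))
    } else NULL

    # primary-treatment events inside the washout; these must never
    # qualify despite carrying matching codes
    pt_sel <- rbinom(n, 1, config$primary_treatment_event_prob) == 1
    pt_ev <- if (any(pt_sel)) {
      n_ev <- ifelse(pt_sel, 1L + rbinom(n, 1, 0.5), 0L)
      idx <- rep(seq_len(n), n_ev)
      offs <- draw_offsets(length(idx), 1, washout)
      event_row_template(
        pt$patient_id[idx], offs, pt$diagnosis_date[idx],
        sample(c("inpatient_procedure", "ambulatory_procedure"),
               length(idx), replace = TRUE),
        cl$procedure_diagnosis$code_sets$procedure$code_system,
        sample_codes(cl$procedure_diagnosis$code_sets$procedure,
                     length(idx)),
        sample_codes(cl$procedure_diagnosis$code_sets$diagnosis,
                     length(idx)),
        ifelse(pt$laterality[idx] %in% c("left", "right"),
               pt$laterality[idx], "unknown"))
    } else NULL

    list(events = bind_rows(sbce_events, fp_ev, pt_ev), death = death)
  })

  registry <- pt %>%
    left_join(gen$death, by = "patient_id") %>%
    mutate(
      death_date = .data$diagnosis_date + .data$death_offset,
      cause_of_death_code = .data$cause) %>%
    select(dplyr::all_of(registry_cols()))

  events <- gen$events %>%
    arrange(.data$patient_id, .data$event_date, .data$source, .data$code)

  truth <- pt %>%
    mutate(true_sbce_date = .data$diagnosis_date + .data$sbce_offset) %>%
    select("patient_id", true_sbce = "true_sbce",
           true_sbce_date = "true_sbce_date",
           contralateral_truth = "contra_truth")

  list(cohort = sbce_cohort(registry, events, config$study_end),
       truth = truth)
}

#' Simulate an imperfect manual record review
#'
#' The reference standard in a validation study is itself fallible:
#' reviewers at one center miss events managed elsewhere, and
#' occasionally call an event that did not happen.  Labels are the
#' ground truth flipped with `review_miss_prob` (on true positives) and
#' `review_false_call_prob` (on true negatives), using the review
#' substream of the config seed — so review noise is independent of the
#' generated utilization given the truth.
#'
#' @param truth Truth tibble from [generate_cohort()].
#' @param config The same [simulation_config()].
#' @return Tibble `patient_id`, `label` (logical).
#' @export
simulate_manual_review <- function(truth, config) {
  stopifnot(inherits(config, "sbce_sim_config"))
  ss <- substream_seeds(config)
  withr::with_seed(ss[["review"]], {
    flip <- ifelse(truth$true_sbce,
                   rbinom(nrow(truth), 1, config$review_miss_prob),
                   rbinom(nrow(truth), 1, config$review_false_call_prob))
    tibble(patient_id = truth$patient_id,
           label = xor(truth$true_sbce, flip == 1))
  })
}

#' Construct a cohort that realizes a target confusion matrix
#'
#' Deterministically (given `seed`) builds a cohort in which the
#' classification algorithm fires for exactly `tp + fp` patients (each
#' given one qualifying radiotherapy event after the washout) and for no
#' one else, together with reference labels positive for exactly
#' `tp + fn` patients, arranged so that [build_confusion()] applied to
#' the algorithm output and the labels reproduces the target exactly.
#' Used for end-to-end pipeline tests against published validation
#' tables.
#'
#' @param target An [confusion_matrix()] object.
#' @param seed Integer seed.
#' @param washout_days Washout length in days (default 180).
#' @param study_end End of follow-up (default `"2013-12-31"`).
#' @return List with `cohort`, `reference` (labels tibble) and
#'   `algorithm_positive` (the patient ids planted to fire).
#' @export
plant_confusion_cohort <- function(target, seed = 1L, washout_days = 180,
                                   study_end = as.Date("2013-12-31")) {
  stopifnot(inherits(target, "sbce_confusion"))
  n <- target$tp + target$fp + target$fn + target$tn
  study_end <- as.Date(study_end)
  withr::with_seed(seed, {
    ids <- sprintf("V%06d", sample.int(n))
    diagnosis_date <- as.Date("2009-01-01") +
      draw_offsets(n, 0, as.integer(as.Date("2012-12-31") -
                                      as.Date("2009-01-01")))
    registry <- tibble(
      patient_id = ids,
      diagnosis_date = diagnosis_date,
      stage = sample(c("I", "II", "III"), n, replace = TRUE,
                     prob = c(701, 812, 732)),
      laterality = sample(c("left", "right"), n, replace = TRUE),
      sex = "female",
      age_at_diagnosis = pmin(95L, pmax(18L,
                                        as.integer(round(rnorm(n, 59, 12))))),
      death_date = as.Date(NA), cause_of_death_code = NA_character_,
      prior_breast_cancer = FALSE, prior_other_cancer = FALSE,
      histology_exclusion_flag = FALSE)

    alg_pos <- ids[seq_len(target$tp + target$fp)]
    gap <- as.integer(study_end - diagnosis_date)
    sel <- match(alg_pos, registry$patient_id)
    events <- tibble(
      patient_id = alg_pos,
      event_date = registry$diagnosis_date[sel] +
        draw_offsets(length(sel), washout_days + 1, gap[sel]),
      source = "radiotherapy", code_system = "RT-SYN", code = "RTBRST",
      diagnosis_code = NA_character_,
      laterality = registry$laterality[sel])

    ref_pos <- c(ids[seq_len(target$tp)],
                 ids[target$tp + target$fp + seq_len(target$fn)])
    reference <- tibble(patient_id = ids, label = ids %in% ref_pos)

    list(cohort = sbce_cohort(registry, events, study_end),
         reference = reference,
         algorithm_positive = alg_pos)
  })
}

#' Write a cohort (and optional truth table) to delimited text
#'
#' Emits `registry.csv`, `events.csv` and, when `truth` is supplied,
#' `truth.csv` in the schemas read by [read_cohort()].  Output is
#' byte-identical for identical inputs.
#'
#' @param cohort An [sbce_cohort()].
#' @param dir Output directory (created if missing).
#' @param truth Optional truth tibble from [generate_cohort()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "sbce_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(registry = file.path(dir, "registry.csv"),
             events = file.path(dir, "events.csv"))
  readr::write_csv(cohort$patients, paths[["registry"]], na = "")
  readr::write_csv(cohort$events, paths[["events"]], na = "")
  if (!is.null(truth)) {
    paths[["truth"]] <- file.path(dir, "truth.csv")
    readr::write_csv(truth, paths[["truth"]], na = "")
  }
  invisible(paths)
}
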