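cl <- test_codelists()

test_that("observation window runs from the washout boundary to censoring", {
  p <- make_patient("p1", diagnosis_date = "2010-01-01")
  win <- observation_window(p, 180, as.Date("2013-12-31"))
  expect_equal(win$window_start, as.Date("2010-06-30"))
  expect_equal(win$window_end, as.Date("2013-12-31"))

  # death caps the window; an early death yields an empty window
  p2 <- make_patient("p2", diagnosis_date = "2012-01-01",
                     death_date = "2012-05-01")
  win2 <- observation_window(p2, 180, as.Date("2013-12-31"))
  expect_equal(win2$window_end, as.Date("2012-05-01"))
  expect_true(win2$window_start >= win2$window_end)
})

test_that("an event dated exactly washout days after diagnosis never qualifies", {

  p <- make_patient("p1", diagnosis_date = "2010-01-01")
  at_boundary <- make_event("p1", as.Date("2010-01-01") + 180,
                            "radiotherapy", "RTBRST",
                            code_system = "RT-SYN")
  past_boundary <- make_event("p1", as.Date("2010-01-01") + 181,
                              "radiotherapy", "RTBRST",
                              code_system = "RT-SYN")
  q1 <- evaluate_criterion(sbce_cohort(p, at_boundary, "2013-12-31"),
                           cl, "radiotherapy")
  q2 <- evaluate_criterion(sbce_cohort(p, past_boundary, "2013-12-31"),
                           cl, "radiotherapy")
  expect_equal(nrow(q1), 0L)
  expect_equal(nrow(q2), 1L)
})

test_that("the procedure criterion requires procedure AND diagnosis codes on the same event", {

  p <- make_patient("p1", diagnosis_date = "2010-01-01")
  both <- make_event("p1", "2011-01-01", "inpatient_procedure", "1YM87",
                     diagnosis_code = "C509")
  proc_only <- make_event("p1", "2011-01-01", "ambulatory_procedure",
                          "1YM87", diagnosis_code = "Z420")
  no_diag <- make_event("p1", "2011-01-01", "inpatient_procedure",
                        "1YM87")
  expect_equal(nrow(evaluate_criterion(
    sbce_cohort(p, both, "2013-12-31"), cl, "procedure_diagnosis")), 1L)
  expect_equal(nrow(evaluate_criterion(
    sbce_cohort(p, proc_only, "2013-12-31"), cl,
    "procedure_diagnosis")), 0L)
  expect_equal(nrow(evaluate_criterion(
    sbce_cohort(p, no_diag, "2013-12-31"), cl,
    "procedure_diagnosis")), 0L)
})

test_that("duplicate rows collapse but distinct events both count", {

  p <- make_patient("p1", diagnosis_date = "2010-01-01")
  dup <- dplyr::bind_rows(
    make_event("p1", "2011-01-01", "radiotherapy", "RTBRST",
               code_system = "RT-SYN"),
    make_event("p1", "2011-01-01", "radiotherapy", "RTBRST",
               code_system = "RT-SYN"))
  two <- dplyr::bind_rows(
    make_event("p1", "2011-01-01", "radiotherapy", "RTBRST",
               code_system = "RT-SYN"),
    make_event("p1", "2011-09-01", "radiotherapy", "RTNODE",
               code_system = "RT-SYN"))
  expect_equal(nrow(evaluate_criterion(
    sbce_cohort(p, dup, "2013-12-31"), cl, "radiotherapy")), 1L)

  res <- classify_cohort(sbce_cohort(p, two, "2013-12-31"), cl)
  rt <- res$criterion_tally[res$criterion_tally$criterion ==
                              "radiotherapy", ]
  expect_equal(rt$n_events, 2L)     # more events than patients
  expect_equal(rt$n_patients, 1L)
})

test_that("the death criterion reads the registry cause of death inside the window", {

  dies_of_bc <- make_patient("p1", diagnosis_date = "2010-01-01",
                             death_date = "2012-03-01",
                             cause_of_death_code = "C509")
  dies_other <- make_patient("p2", diagnosis_date = "2010-01-01",
                             death_date = "2012-03-01",
                             cause_of_death_code = "I219")
  cohort <- sbce_cohort(dplyr::bind_rows(dies_of_bc, dies_other),
                        empty_events(), "2013-12-31")
  q <- evaluate_criterion(cohort, cl, "death_breast_cancer")
  expect_equal(q$patient_id, "p1")
  expect_equal(q$event_date, as.Date("2012-03-01"))
})

test_that("one qualifying event of one criterion suffices; washout-only events do not", {

  p <- make_patient("p1", diagnosis_date = "2010-01-01")
  one_sys <- make_event("p1", "2011-06-01", "systemic_therapy", "SYS001",
                        code_system = "DRUG-SYN")
  res <- classify_patient(p, one_sys, cl, study_end = "2013-12-31")
  expect_true(res$is_sbce)
  expect_equal(res$criteria_met, "systemic_treatment")
  expect_equal(res$first_event_date, as.Date("2011-06-01"))

  washout_only <- make_event("p1", "2010-03-01", "inpatient_procedure",
                             "1YM87", diagnosis_code = "C509")
  res2 <- classify_patient(p, washout_only, cl, study_end = "2013-12-31")
  expect_false(res2$is_sbce)
  expect_equal(res2$criteria_met, "")
})

test_that("classification is invariant under permutation of event order", {

  sim <- generate_cohort(simulation_config(n_patients = 300, seed = 21))
  res <- classify_cohort(sim$cohort, cl)
  shuffled <- sim$cohort
  set.seed(99)
  shuffled$events <- shuffled$events[sample.int(nrow(shuffled$events)), ]
  res_shuf <- classify_cohort(shuffled, cl)
  expect_equal(tidy(res_shuf), tidy(res))
  expect_equal(res_shuf$criterion_tally, res$criterion_tally)
  # and the per-criterion union reproduces the joint classification,
  # so criterion evaluation order cannot matter
  per_crit <- lapply(
    c("radiotherapy", "death_breast_cancer", "systemic_treatment",
      "procedure_diagnosis"),
    function(cid) evaluate_criterion(sim$cohort, cl, cid))
  union_ids <- sort(unique(unlist(lapply(per_crit,
                                         function(q) q$patient_id))))
  expect_equal(sort(tidy(res)$patient_id[tidy(res)$is_sbce]), union_ids)
})

test_that("contralateral flag requires strictly opposite known laterality", {

  p <- make_patient("p1", diagnosis_date = "2010-01-01",
                    laterality = "left")
  ev <- function(lat, src = "radiotherapy", code = "RTBRST",
                 sys = "RT-SYN", diag = NA_character_) {
    make_event("p1", "2011-06-01", src, code, code_system = sys,
               diagnosis_code = diag, laterality = lat)
  }
  flag_of <- function(patient, event) {
    classify_patient(patient, event, cl,
                     study_end = "2013-12-31")$contralateral
  }
  expect_true(flag_of(p, ev("right")))
  expect_false(flag_of(p, ev("left")))
  expect_false(flag_of(p, ev("unknown")))
  expect_false(flag_of(p, ev("bilateral")))
  # unknown primary laterality never flags
  p_unk <- make_patient("p1", laterality = "unknown")
  expect_false(flag_of(p_unk, ev("right")))
  # non-lateralized criteria never flag
  expect_false(flag_of(p, ev("right", src = "systemic_therapy",
                             code = "SYS001", sys = "DRUG-SYN")))
})

test_that("a cohort with no events yields zero rates and tallies", {

  p <- make_patient(c("p1", "p2"))
  res <- classify_cohort(sbce_cohort(p, empty_events(), "2013-12-31"), cl)
  expect_equal(res$sbce_rate, 0)
  expect_equal(sum(res$criterion_tally$n_events), 0L)
  expect_equal(nrow(res$combination_tally), 0L)
})

test_that("cohort classification and tallies match the independent scan oracle", {

  sim <- generate_cohort(simulation_config(n_patients = 400, seed = 77))
  res <- classify_cohort(sim$cohort, cl)
  oracle <- oracle_classify(sim$cohort$patients, sim$cohort$events,
                            sim$cohort$study_end)

  got <- tidy(res)
  expect_equal(got$is_sbce, oracle$classifications$is_sbce)
  expect_equal(got$criteria_met, oracle$classifications$criteria_met)
  expect_equal(got$first_event_date,
               oracle$classifications$first_event_date)
  expect_equal(got$contralateral, oracle$classifications$contralateral)

  tal <- res$criterion_tally
  expect_equal(setNames(tal$n_events, tal$criterion),
               oracle$n_events[tal$criterion],
               ignore_attr = TRUE)
  expect_equal(setNames(tal$n_patients, tal$criterion),
               oracle$n_patients[tal$criterion],
               ignore_attr = TRUE)
  lat <- c("procedure_diagnosis", "radiotherapy")
  expect_equal(tal$n_contralateral_events[match(lat, tal$criterion)],
               unname(as.integer(oracle$n_contralateral_events[lat])))
})

test_that("washout safety, partition and monotonicity hold over random cohorts", {

  for (seed in c(3, 14, 158)) {
    sim <- generate_cohort(simulation_config(n_patients = 250,
                                             seed = seed))
    res <- classify_cohort(sim$cohort, cl)
    # washout safety: no qualifying event at or before the boundary
    offs <- dplyr::left_join(
      res$qualifying_events,
      sim$cohort$patients[, c("patient_id", "diagnosis_date")],
      by = "patient_id")
    expect_true(all(as.integer(offs$event_date - offs$diagnosis_date) >
                      180))
    # the combination cells partition the SBCE patients
    expect_equal(sum(res$combination_tally$n_patients),
                 sum(tidy(res)$is_sbce))
    # events >= patients per criterion with >= 1 patient
    tal <- res$criterion_tally
    expect_true(all(tal$n_events[tal$n_patients > 0] >=
                      tal$n_patients[tal$n_patients > 0]))
    # monotonicity: adding a qualifying event never unsets a flag,
    # removing all events forces all flags off
    extra <- make_event(sim$cohort$patients$patient_id[1:25],
                        "2013-06-01", "radiotherapy", "RTMETA",
                        code_system = "RT-SYN")
    grown <- sbce_cohort(sim$cohort$patients,
                         dplyr::bind_rows(sim$cohort$events, extra),
                         sim$cohort$study_end)
    res_grown <- classify_cohort(grown, cl)
    expect_true(all(tidy(res_grown)$is_sbce >= tidy(res)$is_sbce))
    stripped <- sbce_cohort(
      sim$cohort$patients %>%
        dplyr::mutate(cause_of_death_code = NA_character_),
      empty_events(), sim$cohort$study_end)
    expect_false(any(tidy(classify_cohort(stripped, cl))$is_sbce))
  }
})

test_that("small-cell suppression renders counts 1-5 as <6 without touching the object", {

  p <- make_patient(c("p1", "p2"))
  ev <- make_event("p1", "2011-06-01", "radiotherapy", "RTBRST",
                   code_system = "RT-SYN")
  res <- classify_cohort(sbce_cohort(p, ev, "2013-12-31"), cl)
  sup <- cohort_summary(res, suppress_small_cells = TRUE)
  raw <- cohort_summary(res)
  expect_equal(
    sup$n_patients[sup$criterion == "radiotherapy"], "<6")
  expect_equal(
    raw$n_patients[raw$criterion == "radiotherapy"], "1")
  expect_equal(res$criterion_tally$n_patients[
    res$criterion_tally$criterion == "radiotherapy"], 1L)
})
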