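#' Validation-design assumptions
#'
#' Container for the a-priori quantities behind a stage-stratified
#' validation sample: assumed per-stage SBCE prevalence, the sensitivity
#' and specificity the design should be able to detect, and the planned
#' per-stage sample size.  Defaults are the conventional planning values
#' for early-stage breast cancer over roughly three years of follow-up:
#' prevalence 2% / 7.7% / 20% for stages I / II / III, detectable
#' sensitivity 75% / 85% / 90% and specificity 99% / 95% / 90%, with
#' 1000 patients per stage.
#'
#' @param stage Character vector of stage labels.
#' @param prevalence,sensitivity,specificity Per-stage proportions in
#'   (0, 1).
#' @param n_per_stage Planned patients sampled per stage (default 1000).
#' @return A tibble with one row per stage.
#' @export
design_assumptions <- function(stage = c("I", "II", "III"),
                               prevalence = c(0.02, 0.077, 0.20),
                               sensitivity = c(0.75, 0.85, 0.90),
                               specificity = c(0.99, 0.95, 0.90),
                               n_per_stage = 1000) {
  stopifnot(length(prevalence) == length(stage),
            length(sensitivity) == length(stage),
            length(specificity) == length(stage),
            all(prevalence > 0 & prevalence < 1),
            all(sensitivity > 0 & sensitivity <= 1),
            all(specificity > 0 & specificity <= 1),
            n_per_stage >= 1)
  tibble(stage = stage, prevalence = prevalence,
         sensitivity = sensitivity, specificity = specificity,
         n_per_stage = as.integer(n_per_stage))
}

#' Stage-stratified random sample of patients
#'
#' Draws a uniform sample without replacement of `n_per_stage` patients
#' within each requested stage.  Oversampling advanced stages relative to
#' their population share is the point: SBCEs are rare in early stages,
#' so equal allocation buys enough events to pin down sensitivity.
#' A stratum smaller than `n_per_stage` is taken whole with a warning;
#' an empty stratum yields zero sampled patients with a warning.
#'
#' @param patients Registry tibble with `patient_id` and `stage`.
#' @param n_per_stage Target sample size per stratum (default 1000).
#' @param strata Stage labels to sample (default I, II, III).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return Tibble `patient_id`, `stage` of sampled patients.
#' @export
stratified_sample <- function(patients, n_per_stage = 1000,
                              strata = c("I", "II", "III"), seed = NULL) {
  stopifnot(n_per_stage >= 1)
  draw <- function() {
    purrr::map_dfr(strata, function(s) {
      pool <- patients %>% filter(.data$stage == s)
      if (nrow(pool) == 0L) {
        warn(paste0("Stratum ", s, " is empty; nothing sampled."))
        return(pool %>% select("patient_id", "stage"))
      }
      if (nrow(pool) <= n_per_stage) {
        if (nrow(pool) < n_per_stage) {
          warn(sprintf(
            "Stratum %s has only %d patient(s) (< %d); taking all.",
            s, nrow(pool), n_per_stage))
        }
        return(pool %>% select("patient_id", "stage"))
      }
      pool[sample.int(nrow(pool), n_per_stage), c("patient_id", "stage")]
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Expected observable confidence-interval range for a proportion
#'
#' The planning calculation behind a validation sample: if the true value
#' of a proportion (a sensitivity or a specificity) equals
#' `assumed_value` and it is estimated from `effective_n` subjects, what
#' 95% interval should the study expect to report?  The expected success
#' count is rounded to the nearest integer before interval inversion,
#' and bounds are returned as integer percentages, matching how such
#' ranges are quoted in protocols.
#'
#' @param assumed_value Assumed true proportion(s) in (0, 1].
#' @param effective_n Subjects contributing to the estimate (for a
#'   sensitivity, the expected number of true positives in the stratum;
#'   for a specificity, the rest).  Vectorized with `assumed_value`.
#' @param method Interval method passed to [proportion_ci()].
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble `assumed_value`, `effective_n`, `lower_pct`,
#'   `upper_pct` (integer percentages; `NA` with a warning when
#'   `effective_n` is 0).
#' @export
expected_ci_range <- function(assumed_value, effective_n,
                              method = c("clopper_pearson", "wilson"),
                              conf_level = 0.95) {
  method <- match.arg(method)
  res <- tibble(assumed_value = assumed_value,
                effective_n = as.integer(effective_n))
  if (any(res$effective_n == 0)) {
    warn("effective_n of 0: expected range undefined for that row.")
  }
  ok <- res$effective_n >= 1
  res$lower_pct <- NA_integer_
  res$upper_pct <- NA_integer_
  if (any(ok)) {
    x <- round(res$assumed_value[ok] * res$effective_n[ok])
    ci <- proportion_ci(x, res$effective_n[ok], method = method,
                        conf_level = conf_level)
    res$lower_pct[ok] <- as.integer(round(100 * ci$lower))
    res$upper_pct[ok] <- as.integer(round(100 * ci$upper))
  }
  res
}

#' Per-stage design table
#'
#' Expands [design_assumptions()] into the planning table: expected
#' numbers of SBCE and non-SBCE patients per stratum and the expected
#' observable ranges for sensitivity and specificity.
#'
#' @param assumptions A [design_assumptions()] tibble.
#' @param method Interval method (default Clopper–Pearson).
#' @return Tibble with one row per stage.
#' @export
design_table <- function(assumptions,
                         method = c("clopper_pearson", "wilson")) {
  method <- match.arg(method)
  n_sens <- as.integer(round(assumptions$prevalence *
                               assumptions$n_per_stage))
  n_spec <- assumptions$n_per_stage - n_sens
  sens <- expected_ci_range(assumptions$sensitivity, n_sens, method)
  spec <- expected_ci_range(assumptions$specificity, n_spec, method)
  assumptions %>%
    mutate(
      n_sbce_expected = n_sens,
      n_non_sbce_expected = n_spec,
      sensitivity_lower_pct = sens$lower_pct,
      sensitivity_upper_pct = sens$upper_pct,
      specificity_lower_pct = spec$lower_pct,
      specificity_upper_pct = spec$upper_pct)
}
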