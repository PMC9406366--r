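#' Construct a confusion matrix from counts
#'
#' Counts are patient-level, with the algorithm as the index test and the
#' reference standard (manual record review) as truth; "positive" means
#' an SBCE.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `sbce_confusion`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("Confusion-matrix counts must be non-negative integers.")
  }
  if (sum(counts) == 0) abort("Confusion matrix has no observations.")
  structure(as.list(as.integer(counts)) |> setNames(names(counts)),
            class = "sbce_confusion")
}

#' Cross-classify algorithm labels against a reference standard
#'
#' @param algorithm_labels,reference_labels Tibbles with columns
#'   `patient_id` and `label` (logical; `TRUE` = SBCE).  The two tables
#'   must cover exactly the same patients.
#' @return An [confusion_matrix()] object.
#' @export
build_confusion <- function(algorithm_labels, reference_labels) {
  a <- as_tibble(algorithm_labels)
  r <- as_tibble(reference_labels)
  stopifnot(all(c("patient_id", "label") %in% names(a)),
            all(c("patient_id", "label") %in% names(r)))
  only_a <- setdiff(a$patient_id, r$patient_id)
  only_r <- setdiff(r$patient_id, a$patient_id)
  if (length(only_a) || length(only_r)) {
    abort(paste0(
      "Label tables cover different patients. ",
      "Algorithm-only: ", paste(head(only_a, 5), collapse = ", "),
      if (length(only_a) > 5) ", ..." else "",
      "; reference-only: ", paste(head(only_r, 5), collapse = ", "),
      if (length(only_r) > 5) ", ..." else ""))
  }
  m <- inner_join(a, r, by = "patient_id",
                  suffix = c("_alg", "_ref"))
  confusion_matrix(
    tp = sum(m$label_alg & m$label_ref),
    fp = sum(m$label_alg & !m$label_ref),
    fn = sum(!m$label_alg & m$label_ref),
    tn = sum(!m$label_alg & !m$label_ref))
}

#' @export
print.sbce_confusion <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(algorithm = c("No SBCE", "SBCE"),
                              reference = c("No SBCE", "SBCE")))
  cat("<sbce_confusion>  (rows: algorithm, cols: manual review)\n")
  print(m)
  invisible(x)
}

#' Exact and score confidence intervals for a binomial proportion
#'
#' Clopper–Pearson inverts the exact binomial tails (via the beta
#' quantile identity); Wilson is the score interval.  Vectorized over
#' `x` and `n`.
#'
#' @param x Successes (0 ≤ x ≤ n).
#' @param n Trials (n ≥ 1).
#' @param method `"clopper_pearson"` (default) or `"wilson"`.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return Tibble with columns `x`, `n`, `estimate`, `lower`, `upper`
#'   (proportions).
#' @export
proportion_ci <- function(x, n, method = c("clopper_pearson", "wilson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(all(n >= 1), all(x >= 0), all(x <= n))
  alpha <- 1 - conf_level
  p <- x / n
  if (method == "clopper_pearson") {
    lower <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
    upper <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  } else {
    z <- qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- pmax(0, centre - half)
    upper <- pmin(1, centre + half)
  }
  tibble(x = x, n = n, estimate = p, lower = lower, upper = upper)
}

# Large-sample standard error of the kappa estimate for two raters and a
# dichotomous outcome, after Fleiss, Cohen & Everitt (1969), eq. for
# var(kappa-hat) not assuming kappa = 0.
fleiss_kappa_se <- function(cm) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  p11 <- cm$tp / n; p12 <- cm$fp / n; p21 <- cm$fn / n; p22 <- cm$tn / n
  p1. <- p11 + p12; p2. <- p21 + p22
  p.1 <- p11 + p21; p.2 <- p12 + p22
  po <- p11 + p22
  pe <- p1. * p.1 + p2. * p.2
  if (pe >= 1) return(NA_real_)
  k <- (po - pe) / (1 - pe)
  a <- p11 * (1 - (p1. + p.1) * (1 - k))^2 +
    p22 * (1 - (p2. + p.2) * (1 - k))^2
  b <- (1 - k)^2 * (p12 * (p.1 + p2.)^2 + p21 * (p.2 + p1.)^2)
  d <- (k - pe * (1 - k))^2
  sqrt(pmax(0, a + b - d) / (n * (1 - pe)^2))
}

#' Diagnostic agreement statistics for a validated algorithm
#'
#' Computes the standard agreement panel for an index test against a
#' reference standard: sensitivity, specificity, positive and negative
#' predictive values, accuracy (observed agreement), Cohen's kappa, and
#' the prevalence-adjusted bias-adjusted kappa (PABAK = 2·accuracy − 1),
#' which is reported alongside kappa because kappa is depressed when the
#' outcome is rare even at high raw agreement.
#'
#' Confidence intervals: exact or score intervals ([proportion_ci()]) for
#' the five proportions; the Fleiss–Cohen–Everitt large-sample interval
#' (kappa ± 1.96·SE) for kappa; and the accuracy interval mapped through
#' 2x − 1 for PABAK, consistent with PABAK's definition.  A statistic
#' with a zero denominator is reported as `NA`; the others are still
#' computed.
#'
#' @param cm An [confusion_matrix()] object.
#' @param ci_method Proportion-CI method, `"clopper_pearson"` (default)
#'   or `"wilson"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `sbce_agreement`; its `stats` element (also
#'   returned by [generics::tidy()]) is a tibble with one row per
#'   statistic (`estimate`, `conf.low`, `conf.high`, proportions on the
#'   0–1 scale).  [format()]/[print()] render percentages to one decimal.
#' @examples
#' agreement_stats(confusion_matrix(tp = 249, fp = 122, fn = 43, tn = 1831))
#' @export
agreement_stats <- function(cm, ci_method = c("clopper_pearson", "wilson"),
                            conf_level = 0.95) {
  stopifnot(inherits(cm, "sbce_confusion"))
  ci_method <- match.arg(ci_method)
  n <- cm$tp + cm$fp + cm$fn + cm$tn

  prop_row <- function(stat, x, d) {
    if (d == 0) {
      return(tibble(statistic = stat, estimate = NA_real_,
                    conf.low = NA_real_, conf.high = NA_real_))
    }
    ci <- proportion_ci(x, d, method = ci_method, conf_level = conf_level)
    tibble(statistic = stat, estimate = ci$estimate,
           conf.low = ci$lower, conf.high = ci$upper)
  }

  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- fleiss_kappa_se(cm)
  kappa_ci <- if (is.na(kappa) || is.na(se)) {
    c(NA_real_, NA_real_)
  } else {
    pmin(1, pmax(-1, kappa + c(-1, 1) * z * se))
  }

  acc <- prop_row("accuracy", cm$tp + cm$tn, n)
  stats <- bind_rows(
    prop_row("sensitivity", cm$tp, cm$tp + cm$fn),
    prop_row("specificity", cm$tn, cm$tn + cm$fp),
    prop_row("ppv", cm$tp, cm$tp + cm$fp),
    prop_row("npv", cm$tn, cm$tn + cm$fn),
    acc,
    tibble(statistic = "kappa", estimate = kappa,
           conf.low = kappa_ci[1], conf.high = kappa_ci[2]),
    tibble(statistic = "pabak", estimate = 2 * po - 1,
           conf.low = 2 * acc$conf.low - 1,
           conf.high = 2 * acc$conf.high - 1))

  structure(list(stats = stats, cm = cm, n = n,
                 observed_agreement = po, expected_agreement = pe,
                 ci_method = ci_method, conf_level = conf_level),
            class = "sbce_agreement")
}

#' @method tidy sbce_agreement
#' @export
tidy.sbce_agreement <- function(x, ...) x$stats

#' @method glance sbce_agreement
#' @export
glance.sbce_agreement <- function(x, ...) {
  wide <- x$stats %>%
    select("statistic", "estimate") %>%
    tidyr::pivot_wider(names_from = "statistic", values_from = "estimate")
  bind_cols(tibble(n = x$n), wide)
}

#' @export
format.sbce_agreement <- function(x, ...) {
  s <- x$stats
  vapply(seq_len(nrow(s)), function(i) {
    if (is.na(s$estimate[i])) {
      sprintf("%s: undefined", s$statistic[i])
    } else {
      sprintf("%s %.1f (%.1f-%.1f)", s$statistic[i],
              100 * s$estimate[i], 100 * s$conf.low[i],
              100 * s$conf.high[i])
    }
  }, character(1))
}

#' @export
print.sbce_agreement <- function(x, ...) {
  cat(sprintf("<sbce_agreement> n = %d, %s %d%% CI\n", x$n, x$ci_method,
              round(100 * x$conf_level)))
  cat(paste0("  ", format(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Forest-style plot of the agreement panel
#'
#' @param object An `sbce_agreement`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sbce_agreement
#' @export
autoplot.sbce_agreement <- function(object, ...) {
  df <- object$stats %>%
    filter(!is.na(.data$estimate)) %>%
    mutate(statistic = factor(.data$statistic,
                              levels = rev(.data$statistic)))
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$estimate,
                                   y = .data$statistic)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = 100 * .data$conf.low,
                                          xmax = 100 * .data$conf.high)) +
    ggplot2::labs(x = "percent (95% CI)", y = NULL,
                  title = "Algorithm agreement with reference standard")
}

#' Apply adjudication overrides to reference labels
#'
#' After manual review, borderline classifications may be re-adjudicated:
#' a reference label is overridden when administrative data contain
#' definitive evidence (e.g. a pathology report), typically flipping
#' review-negative, algorithm-positive patients to positive.  Flip counts
#' by direction are reported via a message.
#'
#' @param reference_labels Tibble `patient_id`, `label` (logical).
#' @param overrides Tibble `patient_id`, `label` with revised labels;
#'   every override patient must exist in `reference_labels`.
#' @return The revised labels tibble (same row order as input).
#' @export
apply_adjudication <- function(reference_labels, overrides) {
  r <- as_tibble(reference_labels)
  o <- as_tibble(overrides)
  if (nrow(o) == 0L) return(r)
  missing_ids <- setdiff(o$patient_id, r$patient_id)
  if (length(missing_ids)) {
    abort(paste0("Override patient(s) not in the reference labels: ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  out <- r %>%
    left_join(o %>% rename(override = "label"), by = "patient_id") %>%
    mutate(new_label = dplyr::coalesce(.data$override, .data$label))
  up <- sum(!out$label & out$new_label)
  down <- sum(out$label & !out$new_label)
  inform(sprintf(
    "Adjudication flipped %d label(s) negative->positive and %d positive->negative.",
    up, down))
  out %>% select("patient_id", label = "new_label")
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic without continuity correction on an r x c count
#' table; used to compare excluded vs retained validation patients across
#' stage.
#'
#' @param table Matrix (or coercible) of non-negative counts with all
#'   row and column sums positive.
#' @return One-row tibble `statistic`, `df`, `p.value`.
#' @export
chi_squared_independence <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("Chi-squared test requires all row and column sums > 0.")
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(statistic = unname(res$statistic),
         df = unname(res$parameter),
         p.value = unname(res$p.value))
}

#' Cochran–Mantel–Haenszel test over stratified 2x2 tables
#'
#' Classical CMH chi-square (1 df, no continuity correction) for
#' association between two binary variables controlling for a stratifier
#' — here, algorithm classification vs manual-review exclusion,
#' controlling for stage at diagnosis.  Strata with a zero row or column
#' total carry no information and are skipped with a warning.
#'
#' @param strata List of 2x2 count matrices, one per stratum.
#' @return One-row tibble `statistic`, `df`, `p.value`,
#'   `n_strata_used`.
#' @export
cmh_test <- function(strata) {
  stopifnot(is.list(strata), length(strata) >= 1)
  mats <- lapply(strata, as.matrix)
  ok <- vapply(mats, function(m) {
    all(dim(m) == c(2, 2)) && all(rowSums(m) > 0) && all(colSums(m) > 0)
  }, logical(1))
  if (any(!ok)) {
    warn(sprintf("Skipping %d degenerate stratum/strata (zero row or column total).",
                 sum(!ok)))
    mats <- mats[ok]
  }
  if (length(mats) == 0) abort("No informative strata remain.")
  # classical CMH: (sum_k (a_k - E_k))^2 / sum_k Var_k with the usual
  # hypergeometric mean and variance of the (1,1) cell per stratum
  a <- vapply(mats, function(m) m[1, 1], numeric(1))
  e <- vapply(mats, function(m) {
    sum(m[1, ]) * sum(m[, 1]) / sum(m)
  }, numeric(1))
  v <- vapply(mats, function(m) {
    nn <- sum(m)
    sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]) /
      (nn^2 * (nn - 1))
  }, numeric(1))
  stat <- sum(a - e)^2 / sum(v)
  tibble(statistic = stat,
         df = 1,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         n_strata_used = length(mats))
}
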