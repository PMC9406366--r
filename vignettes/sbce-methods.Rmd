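---
title: "Identifying second breast cancer events in administrative data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying second breast cancer events in administrative data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbce)
```

## The classification model

Registries capture incident cancers, not recurrences.  The package
infers *second breast cancer events* (SBCEs — recurrence at any site or
a new primary breast cancer) from the utilization trail such events
leave in linked administrative data.  The model is a deterministic rule
engine, not a statistical classifier: given a patient's dated, coded
utilization records, the patient is SBCE-positive if **any one of four
criteria is met a single time** inside the observation window.

The window starts 180 days after diagnosis and ends at death or the
administrative end of follow-up, whichever comes first.  The first 180
days form a *washout*: curative treatment of the incident cancer
(surgery, adjuvant chemotherapy, radiotherapy) generates exactly the
kinds of events the criteria look for, so events in the washout are
attributed to primary management.  The boundary is strict — an event
dated exactly 180 days after diagnosis is washout; a qualifying event
must be *more than* `washout_days` after diagnosis.  Correspondingly,
patients dying within 180 days of diagnosis are excluded from the
cohort: their observation window is empty by construction.

The four criteria read different sources and carry different matching
semantics:

| criterion | sources | semantics |
|---|---|---|
| `death_breast_cancer` | vital statistics | cause-of-death code matches |
| `procedure_diagnosis` | inpatient + ambulatory procedures | procedure code **and** associated diagnosis code match on the *same* event |
| `systemic_treatment` | systemic-therapy records | drug/regimen code matches |
| `radiotherapy` | radiation-treatment records | treatment code matches |

Because the criteria are independent set-membership tests over
independent event streams, classification is invariant to the order in
which criteria or events are examined; the test suite asserts this by
permutation.

### Code lists as configuration

Which codes operationalize each criterion depends on the jurisdiction's
coding systems (ICD-style diagnoses, intervention codes, drug
identifiers), so the code lists are runtime configuration — a YAML file
with one block per criterion, one code per line — rather than package
constants.  Codes are normalized (upper case, trimmed) on load,
duplicates dropped with a warning, and prefix-mode sets reject any pair
where one code is a prefix of another, since the longer code would be
unreachable and almost certainly a curation error.  The shipped default
(`sbce_example_codelists()`) is synthetic and non-clinical; it exists so
that examples, tests and the generator are self-contained.

### Conventions for ambiguous cases

Several details have no single canonical convention; the package fixes
and documents one:

- **Event identity.**  Administrative extracts duplicate rows across
  feeds.  Events are deduplicated on (patient, date, source, code,
  associated diagnosis) before counting, so "events" tallies count
  distinct events.
- **Death criterion.**  Read from the registry's death date and
  cause-of-death code, materialized as a pseudo-event dated at death.
  Death on the study end date counts; death after it is censored.
- **Contralateral flag.**  Among SBCE patients, a *probable
  contralateral second primary* is flagged only when the original
  cancer has a definite side and a qualifying event from a lateralized
  criterion (procedures, radiotherapy) is on the strictly opposite
  side.  Bilateral or unknown laterality on either side never flags:
  the call is "probable", and a conservative rule avoids manufacturing
  second primaries out of missing data.
- **First event date.**  The earliest qualifying event date across all
  criteria; same-day ties across criteria are all recorded and no
  criterion precedence is assigned.
- **Eligibility precedence.**  Excluded patients get the first matching
  reason in the fixed order non-female → age < 18 → stage out of range →
  histology exclusion flag → early death, so reason counts plus the
  retained count always sum to the input count.  The
  breast-lymphoma/breast-skin-cancer exclusion travels as a registry
  flag because the morphology codes that would derive it are
  jurisdiction-specific.  Patients with prior cancers are retained:
  prior disease does not change whether a *post-diagnosis* event trail
  exists.
- **Small-cell suppression.**  Published tables from administrative
  data conventionally render counts 1–5 as "<6"; `cohort_summary()`
  offers this as a formatting option only — computed objects are never
  suppressed.

## Agreement statistics

Validation compares the algorithm (index test) against a manual record
review (reference standard) in a 2×2 confusion matrix.  With observed
agreement $p_o = (TP+TN)/n$ and chance agreement
$p_e = p_{1\cdot}p_{\cdot 1} + p_{2\cdot}p_{\cdot 2}$ from the margins:

$$\kappa = \frac{p_o - p_e}{1 - p_e}, \qquad \text{PABAK} = 2p_o - 1.$$

PABAK is reported alongside κ because κ is depressed at low outcome
prevalence even when raw agreement is high (the "kappa paradox"); PABAK
is the value κ would take under balanced margins and equals an affine
map of accuracy.

Interval choices, each genuinely open and fixed as follows:

- **Proportions** (sensitivity, specificity, PPV, NPV, accuracy): exact
  Clopper–Pearson by default, computed by beta-quantile inversion of
  the binomial tails; the Wilson score interval is offered as an
  option.  Exact intervals are conservative (coverage ≥ the nominal
  level), which the test suite verifies by simulation.
- **Kappa**: the Fleiss–Cohen–Everitt (1969) large-sample standard
  error of $\hat\kappa$ (the non-null variance, with the bias term),
  as $\hat\kappa \pm z_{0.975}\,\widehat{SE}$, truncated to [−1, 1].
  This variant reproduces published validation intervals of this form
  to the printed decimal.
- **PABAK**: the accuracy interval mapped through $2x-1$.  Since PABAK
  *is* an affine function of accuracy, any other choice would be
  inconsistent with its definition.
- A statistic with a zero denominator (e.g. sensitivity when the
  reference has no positives) is reported `NA`; the rest of the panel
  is still computed.

The exclusion-bias tests — Pearson chi-squared on an r×c table and the
classical Cochran–Mantel–Haenszel chi-square over stratified 2×2
tables — are both computed without continuity correction, the modern
default.  The CMH statistic is evaluated from its defining
hypergeometric form (so a single stratum reduces exactly to the score
statistic); the test suite cross-checks it against
`stats::mantelhaen.test()`.  Strata with a zero row or column total
carry no information and are skipped with a warning.

## Validation-sample design

SBCEs are rare in early-stage disease, so a validation sample drawn
proportionally to the population would contain too few events to pin
down sensitivity.  The design module implements the standard remedy:
equal-allocation stage-stratified sampling (default 1000 patients per
stage, stages I–III), plus the a-priori planning calculation — given an
assumed prevalence and an assumed sensitivity/specificity, what 95%
interval should the study expect to report?

```{r design}
design_table(design_assumptions())
```

The expected success count (prevalence × n per stage × assumed value)
is rounded to the nearest integer before interval inversion, and bounds
are reported as integer percentages — the paper-protocol convention.
With exact Clopper–Pearson inversion, the stage-II and stage-III
specificity ranges come out at 93–96% and 88–92%; the very small
stage-I sensitivity denominator (≈20 expected events) makes the lower
bound sensitive to the inversion convention, and published versions of
this calculation can differ from exact inversion by about one
percentage point there.  The package documents rather than resolves
that discrepancy: it reports the exact-inversion value.

This is an *expected observable range* calculation, not a formal power
analysis; no hypothesis test is implied.

## The synthetic cohort generator

Real linked health data cannot be shipped, so the generator emulates
the joint structure the algorithm consumes, with known ground truth:

- **Patients**: stage mix defaulting to an incident early-breast-cancer
  population (4.8% / 42.7% / 38.2% / 14.3% for stages 0/I/II/III),
  diagnosis dates uniform over a four-year accrual window, laterality
  left/right with a small unknown fraction.
- **Truth**: per-stage true-SBCE probabilities default to 2% / 7.7% /
  20% for stages I–III — the planning assumptions above — and 4% for
  stage 0, loosely calibrated to observed algorithm rates in that
  stage.  True event dates are uniform in the post-washout window; a
  timing distribution is not identifiable from published sources, and
  uniformity is the least-assumption default.
- **Observation model**: a true SBCE is entirely invisible with
  probability 0.10 (endocrine-only therapy in patients whose drug
  coverage is not captured, or palliative care — mechanisms known to
  cause false negatives in claims algorithms); otherwise each criterion
  independently emits ≥1 qualifying event with its *detectability*
  (defaults 0.05 / 0.65 / 0.35 / 0.40 for death / procedure / systemic /
  radiotherapy, echoing the relative criterion frequencies observed in
  validation cohorts of this kind).  When the death criterion fires,
  the death date is placed at or after the patient's other planted
  events, so censoring never swallows a planted event and the
  probability that a true SBCE is algorithm-detectable is exactly
  $(1 - p_{\text{invis}})\bigl(1 - \prod_c (1 - d_c)\bigr)$ — the
  closed form the parameter-recovery tests check against.
- **Negatives**: with probability 0.06, a patient without a true SBCE
  emits one criterion-matching event after the washout (delayed
  reconstruction, prophylactic surgery), the dominant false-positive
  mechanism; most patients also carry matching *primary-treatment*
  events inside the washout, which must never qualify.
- **Reference standard**: the simulated manual review flips truth with
  a miss probability of 0.05 (care received at another center) and a
  false-call probability of 0.01, independently of the generated
  utilization given the truth.
- **Seeding**: one master seed drives three independent substreams
  (patients+truth, events, review), so changing review noise leaves the
  cohort byte-identical.

`plant_confusion_cohort()` is the deterministic counterpart: given any
target 2×2 confusion matrix it constructs a cohort and reference labels
that realize the matrix exactly through the full pipeline, which is how
the acceptance script reproduces a published validation table without
the underlying data.

### What passing tests do and do not show

The generator produces events that always resolve against the shipped
code lists, uses a single merged events table, has no background
(non-breast-cancer) mortality, and draws event dates uniformly.  Real
administrative data have miscoded and orphan records, source-specific
file layouts, deaths competing with observation, and strongly
non-uniform treatment timing.  Tests passing on synthetic data
therefore demonstrate that the *logic* is correct — windows, matching,
deduplication, tallies, agreement arithmetic — not that any particular
code list achieves any particular accuracy on real data.  Clinical
validity of a code list is explicitly out of scope.

## Problem sizes and numerical notes

The test suite runs the full pipeline at cohort sizes of 150–5000 for
behavioural tests and 20,000 for stochastic parameter-recovery checks
(three Monte-Carlo standard errors of tolerance around closed-form
targets); the proportion-interval coverage check uses 10,000 binomial
replicates at n = 292.  These sizes give Monte-Carlo noise well below
the asserted tolerances while keeping a full run in tens of seconds.

Degenerate inputs are handled explicitly: empty observation windows
(possible when death precedes the washout boundary upstream of
eligibility filtering) are valid and yield no qualifying events; empty
event tables classify everyone negative; zero-denominator statistics
are `NA`; degenerate CMH strata are skipped; `expected_ci_range()` with
zero effective n is flagged undefined.  All date arithmetic is in whole
days on ISO calendar dates — administrative sources report dates, not
times, and day arithmetic keeps every boundary exact.

## Known limitations

- The algorithm cannot distinguish local, regional and distant
  recurrence from a new primary (beyond the probable-contralateral
  flag), and dates an SBCE only by its first qualifying event.
- Sensitivity is structurally limited by treatments invisible to
  administrative data; the invisible fraction is a generator parameter
  here but an unknown in reality.
- The reference-standard simulator models review error as independent
  Bernoulli noise given truth; real review errors correlate with care
  fragmentation and record availability.
- Inter-rater variability of the manual review and multi-rater
  agreement statistics are out of scope.
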