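# sbce

Identify second breast cancer events (SBCEs) in linked administrative
health data, and validate the identification against a reference
standard.

## The problem

Cancer registries record incident diagnoses but not recurrences.
Measuring breast cancer recurrence at the population level therefore
means inferring it from the utilization trail a recurrence leaves in
administrative data: repeat breast surgery, renewed systemic therapy,
renewed radiotherapy, or death from breast cancer.  `sbce` implements a
rule-based algorithm of this kind for registry analysts and health
services researchers, together with the full apparatus needed to
validate it: agreement statistics against a manual record review,
stratified validation-sample design calculations, and a synthetic
administrative-cohort generator with known ground truth so the entire
pipeline can be exercised without access to real health data.

An SBCE is defined as a local, regional, or distant recurrence **or** a
new primary breast cancer, observed more than 180 days after the
incident diagnosis.  The first 180 days are a *washout window*:
breast-cancer-related events in that window are attributed to management
of the initial cancer.

## The algorithm

For each patient, events are scanned from 180 days post-diagnosis to
death or the administrative end of follow-up.  A patient is classified
as having an SBCE on meeting **any one of four criteria a single
time**:

1. *death from breast cancer* — cause-of-death code matches the breast
   cancer code set;
2. *procedure and associated diagnosis* — a single procedure event
   carries both a matching procedure code and a matching associated
   diagnosis code;
3. *systemic treatment* — a systemic-therapy record matches the drug
   code set;
4. *radiotherapy* — a radiation-treatment record matches the
   radiotherapy code set.

Criteria are independent and can be applied in any order.  For the two
lateralized criteria (2 and 4), a qualifying event on the side strictly
opposite the original cancer flags a *probable contralateral second
primary*.  The code sets that operationalize each criterion are runtime
configuration (a YAML file, schema in
`inst/extdata/codelists_schema.yaml`); the package ships a synthetic,
non-clinical default (`sbce_example_codelists()`) used by all examples
and tests.

Validation compares the algorithm (index test) with a manual record
review (reference standard) in a 2×2 table with cells TP, FP, FN, TN and
n = TP+FP+FN+TN, reporting

- sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
  NPV TN/(TN+FN),
- accuracy = observed agreement p₀ = (TP+TN)/n,
- Cohen's κ = (p₀ − pₑ)/(1 − pₑ) with pₑ the marginal chance agreement,
  with the Fleiss–Cohen–Everitt large-sample confidence interval,
- PABAK = 2·p₀ − 1, the prevalence- and bias-adjusted kappa,

with exact Clopper–Pearson intervals (Wilson optional) for the
proportions.  Pearson chi-squared and Cochran–Mantel–Haenszel tests are
provided for exclusion-bias analyses, and `design_table()` reproduces
the a-priori planning calculation for a stage-stratified validation
sample (expected observable CI ranges at assumed prevalence, sensitivity
and specificity).

## Worked example

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

```r
library(sbce)

cl  <- read_codelists(sbce_example_codelists())
sim <- generate_cohort(simulation_config(n_patients = 5000, seed = 42))
res <- classify_cohort(sim$cohort, cl)
res
#> <sbce_classification> 5000 patients, 525 with an SBCE (10.5%), 25 probable contralateral
#> # A tibble: 4 × 4
#>   criterion           n_patients n_events n_contralateral_events
#>   <chr>                    <int>    <int>                  <int>
#> 1 death_breast_cancer         19       19                     NA
#> 2 procedure_diagnosis        475      529                     26
#> 3 systemic_treatment          91      115                     NA
#> 4 radiotherapy               107      147                     22
```

The synthetic cohort plants true SBCEs at stage-specific rates
(2% / 7.7% / 20% for stages I / II / III); the algorithm recovers 10.5%
because some true events leave no administrative trace (endocrine-only
or palliative management) while some negatives emit matching events
(e.g. delayed reconstruction).  Note that each criterion finds more
events than patients — patients can meet a criterion repeatedly.

Validating against a simulated (imperfect) manual review:

```r
review <- simulate_manual_review(sim$truth,
                                 simulation_config(n_patients = 5000, seed = 42))
alg <- dplyr::transmute(tidy(res), patient_id, label = is_sbce)
agreement_stats(build_confusion(alg, review))
#> <sbce_agreement> n = 5000, clopper_pearson 95% CI
#>   sensitivity 65.0 (59.8-69.9)
#>   specificity 93.7 (93.0-94.4)
#>   ppv 44.2 (39.9-48.6)
#>   npv 97.2 (96.7-97.7)
#>   accuracy 91.6 (90.8-92.4)
#>   kappa 48.2 (44.0-52.4)
#>   pabak 83.3 (81.7-84.8)
```

Here both the algorithm and the review err relative to the ground
truth, so the panel measures their agreement, not the algorithm's true
accuracy — exactly the situation a real validation study is in.  The
gap between κ (48%) and PABAK (83%) illustrates why PABAK is reported:
at low outcome prevalence, κ is depressed even when raw agreement is
high.

A command-line front end over the same functions is installed at
`system.file("cli", "sbce.R", package = "sbce")` with subcommands
`simulate`, `classify`, `evaluate` and `design`.

## Limitations

The shipped code lists are synthetic stand-ins, not clinically curated
lists; replace them before any use on real data.  The algorithm does not
distinguish local from regional or distant recurrence, nor date SBCE
onset beyond the first qualifying event.  See the methods vignette
(`vignettes/sbce-methods.Rmd`) for the model, numerical choices, and
what the synthetic generator does and does not emulate.
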