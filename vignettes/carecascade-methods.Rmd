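---
title: "Methods: cascade-of-care and ACIC quality assessment from claims and lab data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade-of-care and ACIC quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecascade)
```

# The measurement model

Quality of chronic care has three dimensions — structure, process and
outcome — and this package operationalizes all three for type 2 diabetes
(T2D) in a setting where no disease register exists and diagnoses are not
recorded in administrative data:

* **Structure** is measured per GP practice with the ACIC instrument
  (Assessment of Chronic Illness Care): six Chronic Care Model subscales,
  each assessed by three or more interview items scored 0–11. The subscale
  score is the arithmetic item mean and the overall score the unweighted
  mean of the six subscale means, so subscales are equally weighted
  regardless of their item counts.
* **Process and outcome** are measured per patient as a cascade of care:
  *tested, diagnosed, in care, in treatment, followed up, under control*.
  The diagnosed cohort is identified algorithmically from claims proxies
  because claims carry no diagnoses; all further stages are rule
  evaluations over dated, coded events.

The two levels are joined by an emulated pseudonymized record linkage, and
analysed jointly with logistic and random-intercept multilevel models
(patients nested in practices).

# Cohort identification and its assumptions

The cohort (= cascade stage 2) for treatment year $x$ is defined in the
selection year $x-1$:

* **Inclusion**: at least one dispense of an antidiabetic of class
  metformin (ATC `A10BA`), sulfonylurea (`A10BB`) or insulin (`A10A`), or a
  pre-diabetes-pass registration (a care-trajectory reimbursement used here
  as a diagnosis proxy), in year $x-1$.
* **Exclusion**: a T1D-convention or insulin-pump registration in $x-1$ or
  $x-2$ — these reimbursements are specific to type 1 diabetes, so they
  remove probable T1D insulin users from the T2D cohort.
* **Age**: "above 40" in year $x-1$. We read this strictly (age $\ge 41$),
  with age computed as $(x-1) - \text{birth year}$ because claims carry
  birth years, not birth dates; `age_inclusive = TRUE` switches to
  $\ge 40$. The strict reading is the default because an exact-age-40
  patient is not "above 40"; the boundary affects one birth cohort only.

The identification is assumption-laden in a documented way: diet-only T2D
patients without a pre-diabetes pass are invisible to the algorithm, and
any T1D patient without the two exclusion registrations is
misclassified as T2D. These are properties of the measurement design, not
of the implementation.

# Stage rules and numerical choices

All windows are closed intervals of whole calendar years, because the
framework specifies year-level windows only. Within that:

* **Tested** (stage 1): ≥1 billed blood glucose or HbA1c test in
  $[x-3, x-1]$, evaluated retrospectively on the cohort. Billed lab-test
  claims carry an `analyte` column precisely so that this stage (and the
  stage-5 test indicators) remain computable for patients whose laboratory
  delivered no result values.
* **In care** (stage 3): ≥1 GP-visit claim in $x-1$ for fee-for-service
  patients. Capitation practices do not bill individual GP visits (a
  registration artifact of the payment system), so capitation patients use
  the alternative indicator: ≥1 GP-prescribed medication or lab test in
  $x-1$. `in_care_sensitivity = TRUE` applies the prescription indicator to
  everyone; by construction this can only change fee-for-service patients,
  and both component indicators are always reported for comparison.
* **In treatment** (stage 4): antidiabetic dispense in year $x$, or — for
  patients who entered via the pre-diabetes pass, who typically take no
  medication — a diabetes-education or dietician consult in year $x$.
* **Followed up** (stage 5): six indicators evaluated in the 12 months of
  calendar year $x$ (a 24-month $x..x+1$ reading is available via
  `followup_window = "24m"`). The HbA1c frequency rule "≥2 measurements, at
  least one in 6 months" is ambiguous; the default reading requires at
  least one measurement in each half of the window, the alternative
  (`hba1c_spacing = "any"`) only ≥2 in total. Both are implemented because
  the choice changes the indicator for patients whose two tests fall in the
  same half-year. The lipid indicator accepts either an LDL-c test or a
  full panel (total cholesterol, HDL, triglycerides). eGFR is computed with
  the CKD-EPI 2009 creatinine equation (sex- and age-adjusted, no race
  term) whenever a linked creatinine value exists; a billed creatinine test
  without a linked value still satisfies the indicator (the test occurred),
  with eGFR set missing.
* **Under control** (stage 6): most recent HbA1c of year $x+1$ strictly
  below 53 mmol/mol (IFCC units throughout; the DCCT% conversion helper is
  display-only). Ties on the last date are averaged — a deterministic
  tie-break that avoids depending on row order. Patients without a linked
  HbA1c in $x+1$ are *unknown*: they are excluded from the stage-6
  denominator rather than counted uncontrolled, and the excluded count is
  reported, because with 1/4 of patients unlinked the
  count-as-uncontrolled convention would bias the outcome bar downward by
  construction. The exploratory four-level stratification uses cut points
  48/53/64 mmol/mol by default; only the 53 dichotomy is normative, the
  bands are configuration.

Bars for stages 1 and 3–5 use the diagnosed cohort as the common
denominator (the cohort *is* stage 2); leakage is additionally reported as
conditional retention between consecutive stages, since bar charts alone do
not fix a denominator convention. Degenerate strata (zero cohort members)
are omitted with a warning rather than producing 0/0.

# The linkage emulation

The organizational linkage flow — two trusted third parties exchanging
encrypted identifiers and single-use random transport numbers over a
sequence of administrative steps — is collapsed into its three
computational stages: (1) keyed pseudonymization of the national identifier
on the claims side and resolution+pseudonymization of the lab-side patient
keys; (2) replacement of pseudonyms by random single-use transport numbers;
(3) assignment of final researcher-side `patient_id`s and the join. A
step-by-step audit log stands in for the administrative flow. The
pseudonymization is a keyed FNV-style hash with deterministic collision
disambiguation: injectivity and determinism are the tested contract,
cryptographic strength is explicitly out of scope. The privacy property
that matters downstream — no national identifier occurs anywhere in
researcher-facing output — is checked content-wise by `privacyAudit()`,
invariant to row and column order.

Each patient uses one laboratory for all results, and non-linkage is
attributed entirely to whole laboratories not participating; the linked
fraction therefore equals the patient share of the participating labs.
Unlinked patients keep their complete claims-side record, so process
indicators remain evaluable for them; only result values (stage 6, eGFR)
become unknown.

# What the generator emulates — and what it does not

`simulateClaims()` is a study-design emulator, not a disease model. Its
defaults are the framework's study conditions: 66 practices in the three
organizational types (44/12/10 mono-FFS / multi-FFS / multi-capitation, GP
head counts averaging ≈4.2 per practice for ≈277 GPs), a 40+ insured
population of ≈86,000 (negative-binomial practice sizes, mean 1300), an
identifiable T2D prevalence of 4.2%, a three-year observation window, and
12 laboratories of which 8 participate. Under uniform (round-robin) lab
assignment 8/12 would link two thirds of the cohort; the observed linkage
success the framework reports is higher (≈74%), which is only consistent
with the participating labs being the larger ones. The default therefore
assigns labs with sizes weighted so the participating labs jointly cover
73.8% of patients; `lab_assignment = "round_robin"` gives the uniform
variant.

Every intended truth label is realized as events that make the
corresponding stage rule evaluate to that label: cohort membership as
selection-year dispenses or a pre-diabetes pass; T1D decoys (10% of
medication users by default, a rate chosen to exercise the exclusion rules,
not an epidemiological estimate) as insulin plus a T1D registration;
glycaemic control as a truncated-normal HbA1c below/at-or-above 53 mmol/mol
(controlled: mean 46, sd 4; uncontrolled: mean 64, sd 8) as the *last*
measurement of $x+1$, with occasional earlier measurements on the other
side of the threshold to exercise the recency rule. Stage retentions are a
conditional chain — stage $s$ intended only if stage $s-1$ was intended,
with configurable per-stage probabilities, optionally overridden by
practice type and vulnerability — so the engine's conditional retention
rates are directly comparable to the configured parameters. The default
retentions (0.95/0.90/0.80/0.70/0.60 for stages 1, 3–6) are illustrative:
no observed per-stage retention is available to calibrate against, and
they are documented as such.

Event dates are uniform within the year an indicator requires;
vulnerability is an abstract Bernoulli stratifier (the underlying
socio-economic construct is not operationalized in claims); costs are
lognormal fillers required by the entity schema but consumed by no
indicator. The generator deliberately omits disease progression, mortality,
seasonality, multi-lab patients, and realistic billing-code catalogues.
Passing tests therefore demonstrate that the *machinery* — identification,
linkage, stage rules, aggregation, models — is correct under the stated
design, not that real Belgian claims would yield these bars.

# The analysis layer

Drop indicators are defined conditionally (failing stage $k$ among patients
passing stage $k-1$), since "leakage" has no formal definition in the
framework. `dropRegressions()` fits one bivariate logistic model per
covariate plus one multivariable model (default covariate set: sex, age,
vulnerability, scheme, practice type, overall ACIC — the framework names
examples, not a fixed set); degenerate outcomes and apparent separation are
flagged with no estimates fabricated. `multilevelFit()` is a
random-intercept logistic model via `lme4::glmer` with the practice
intercept variance reported; either the overall ACIC or individual
subscales can enter as practice covariates (neither is canonical). No
multiple-testing correction is applied by default and the output metadata
says so. ACIC consensus between the two raters is resolved by an explicit
per-item resolution table (the generator uses the rounded rater mean),
keeping the pipeline deterministic where the real procedure is a
discussion.

# Problem sizes and determinism

Generation, linkage and reporting are pure functions of their
configurations; reruns are byte-identical. The test suite exercises the
rule layer on hand-built micro-bundles, equivalence with brute-force
oracles (cohort rules, naive identifier join, IRLS logistic solver) on
bundles of ≤250 patients, and parameter recovery (retentions within 3
binomial standard errors, injected log-odds effects within 2 standard
errors) on simulated populations of roughly 2,500–5,000 patients with
12–16 practices, and 40–50 practices × 80–120 patients for the multilevel
recovery checks — sizes at which the binomial standard errors are small
enough for the checks to be informative. The acceptance script runs the
full default design (66 practices, ≈86,000 patients) in a few seconds.

# Known limitations

* The cohort algorithm inherits the proxies' blind spots (diet-only T2D,
  unregistered T1D); no sensitivity/specificity claim is made.
* The linkage emulation attributes all non-linkage to lab participation;
  other real-world causes (identifier errors, multi-lab patients) are not
  modelled.
* Hospitalizations are carried for schema completeness; no indicator
  consumes them.
* The ACIC generator draws items around a practice-level latent mean; it
  does not model item-level difficulty structure or rater bias beyond a
  shared offset.
* The four-level control stratification and the 24-month follow-up window
  are exploratory options, not validated cut points.
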