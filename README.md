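# carecascade

Quality assessment of integrated type 2 diabetes (T2D) care from linked
health-insurance claims and laboratory data, for health-services researchers
working in fragmented data landscapes (the motivating setting is Belgian
primary care, where no diabetes register exists and claims, lab and
practice-level data live in separate systems).

The package implements a multilevel data framework that combines two
complementary quality models:

* **Cascade of care (CoC)** — process and outcome quality at the patient
  level, as six sequential stages: *tested → diagnosed → in care → in
  treatment → followed up → under control*. Each bar is the percentage of the
  diagnosed cohort meeting the stage's operational rule; attrition between
  consecutive stages ("leakage", reported as conditional drop rates) locates
  where patients are lost.
* **Chronic Care Model, scored with the ACIC instrument** — structure quality
  at the GP-practice level: six subscales (organization, community linkages,
  self-management support, decision support, delivery system design, clinical
  information systems), items scored 0–11, subscale score = item mean,
  overall ACIC = mean of the six subscale means.

Because the real claims and lab extracts are access-restricted, the package
ships a seeded synthetic-data generator that emulates the framework's
entity-relationship model (patients, practices, claims, pharmaceuticals,
ATC-coded; lab results, LOINC-coded; hospitalizations) with configurable
per-stage cascade retention, so every downstream component is testable
end-to-end. Real-use mode accepts the same CSV schemas
(`inst/extdata/schema.yaml`).

## The operational core

With treatment year *x* (selection year *x−1*, control year *x+1*):

* **Diagnosed (cohort)** — age > 40 in *x−1* and (≥1 dispense of metformin /
  sulfonylurea / insulin, ATC `A10BA`/`A10BB`/`A10A`, or a pre-diabetes-pass
  registration in *x−1*), excluding patients with a T1D-convention or
  insulin-pump registration in *x−1* or *x−2*.
* **Tested** — ≥1 billed glucose/HbA1c test in *x−3..x−1*.
* **In care** — ≥1 GP visit in *x−1*; for capitation patients (whose GP
  visits are not billed) ≥1 GP-prescribed medication or lab test in *x−1*.
* **In treatment** — T2D medication in *x*, or (pre-diabetes trajectory) a
  diabetes-education/dietician consult in *x*.
* **Followed up** — six indicators in year *x*: ≥2 HbA1c (≥1 per half-year),
  lipid profile, microalbuminuria, creatinine (with CKD-EPI eGFR),
  foot exam, ophthalmologist; reported individually and as their conjunction.
* **Under control** — most recent HbA1c of *x+1* < 53 mmol/mol (IFCC).

Patient-side records and lab-side records are joined by an emulation of
deterministic pseudonymized linkage through two trusted third parties
(keyed identifier encryption, single-use random transport numbers), with a
privacy audit asserting that no national identifier reaches researcher-facing
output. Cascade drops can then be modelled with logistic regressions and
random-intercept multilevel models (patients within practices, practice-level
ACIC effects).

## Worked example

```r
library(carecascade)

cfg <- simConfig(seed = 42,
                 n_practices_per_type = c(mono_ffs = 8, multi_ffs = 4,
                                          multi_capitation = 4),
                 patients_per_practice = list(mean = 300, dispersion = 8))
sim <- simulateClaims(cfg)

cc  <- cascadeConfig(year_x = 2018)
sel <- selectCohort(sim$bundle, cc)
sel$exclusion_log
#>          n_patients n_meeting_inclusion       n_removed_age
#>                4361                 215                   0
#>       n_removed_t1d            n_cohort
#>                  17                 198

linked <- linkClaims(sim$bundle, sel$cohort, seed = 43)
linked
#> linked_dataset: 198 cohort patients, 158 linked (79.8%)
#>   lab results: 886 (dropped unmatched: 1511)

cascade <- buildCascade(linked, cc)
cascade
#> cascade_result: 198 cohort patients
#>   tested          97.0%  (192/198)
#>   in_care         91.9%  (182/198)
#>   in_treatment    72.7%  (144/198)
#>   followed_up     49.5%  (98/198)
#>   under_control   60.3%  (70/116)
```

Reading the output: of 4361 insured 40+ patients, 198 (4.5%) are identified
as the T2D cohort by the medication / pre-diabetes-pass algorithm (17
medication users were excluded as probable type 1 patients). 158 cohort
patients (79.8%) could be linked to lab results because their laboratory
delivers data. The bars are percentages of the 198 diagnosed patients —
except *under control*, which is computed over the 116 patients with a known
HbA1c in the control year (unlinked patients have no lab values; their count
is reported, not imputed as uncontrolled). The `dropped unmatched` count is
lab results of non-cohort patients that the linkage discards.

Practice-level structure scores and figures:

```r
acic  <- acicScoreTable(generateAcicSurveys(cfg, sim$bundle$practices))
round(mean(acic$acic_overall), 2)
#> [1] 5.55
rep <- renderReport(cascade, acic, sim$bundle$practices, out_dir = "report")
frame <- buildFrame(cascade, acic)
multilevelFit(frame, "stage4_in_treatment")
```

`runAll(runConfig(sim = cfg), out_dir = "run")` chains every stage
(simulate → cohort → link → cascade → ACIC → report) and writes all
artifacts plus a manifest; `inst/cli/carecascade.R` exposes the same stages
as shell subcommands.

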