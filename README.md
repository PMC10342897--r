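# pedhtn

Guideline-based pediatric hypertension surveillance from outpatient
blood-pressure (OBP) records.

## The problem

In children, hypertension is defined against *normative* blood pressure:
below age 13 (2017 American Academy of Pediatrics guideline) or 18 (2004
Fourth Report), a reading is abnormal when it crosses a percentile cutoff
in a reference distribution indexed by sex, age, and **height percentile**
— and a diagnosis requires at least three qualifying readings on separate
occasions within one year of age. Screening routine outpatient EHR
vital-sign panels for hypertension therefore means resolving per-visit
thresholds, cleaning messy longitudinal data, and counting occasions per
person-year — under two rule sets that disagree for adolescents, where the
AAP guideline replaces percentiles with static cutoffs:

| context | elevated / prehypertension | hypertension |
|---|---|---|
| Fourth Report, 1–17 y | min(P90, 120/80) | P95 + 5 mmHg |
| AAP 2017, 1–12 y | min(P90, 120/80) | min(P95, 130/80) |
| AAP 2017, 13–17 y | ≥ 120 and/or ≥ 80 | ≥ 130 and/or ≥ 80 |
| both, 18–20 y | 120/80 floor | ≥ 140 and/or ≥ 90 |

`pedhtn` implements the full surveillance pipeline for epidemiologists and
EHR analysts:

* **LMS normative engine** — z = ((x/M)^L − 1)/(L·S) growth z-scores,
  height percentiles, and table-driven resolution of both guidelines'
  cutoffs (`lms_zscore`, `height_percentile`, `resolve_thresholds`);
* **cohort QC** with attrition accounting — complete BP pairs, height
  present, ±6 SD growth screen, BP plausibility bounds (60–240 / 30–160
  mmHg, inclusive), ≥ 3 distinct-date occasions (`run_qc`);
* **person-year classification** under both guidelines — ≥ 3 SBP and/or
  ≥ 3 DBP qualifying occasions within one year of age
  (`classify_cohort`);
* **statistics** — rates per 1000 persons, annual trend, Cohen's κ with
  Fleiss–Cohen–Everitt SE, 95% CI and interpretation bands, BMI
  categories at the 5/85/95 percentile breaks, odds-ratio association
  analysis (`event_rate`, `cohens_kappa`, `guideline_agreement`,
  `bmi_category`, `logistic_or`);
* **medical complexity** — conservative PMCA levels from ICD-9/10
  diagnosis histories (`classify_pmca`);
* **synthetic EHR generator** with known ground truth so every stage is
  testable without protected data (`gen_cohort`).

Real guideline tables and PMCA code lists are user-supplied plug-ins in
documented delimited schemas (`read_bp_reference`, `read_code_map`);
synthetic equivalents ship for tests.

## Worked example

Simulate a 400-person outpatient panel with 3% planted hypertension
prevalence, run the whole pipeline, and read the report:

```r
library(pedhtn)
cfg <- sim_config(n_persons = 400, htn_prevalence = 0.03,
                  elevated_prevalence = 0.04, condition_rates = 0.05,
                  seed = 2718)
sim <- gen_cohort(cfg)
res <- run_pipeline(sim$visits, sim$growth_ref, sim$bp_tables,
                    sim$encounters, sim$code_map)
res$qc$attrition
#>             stage records_in records_excluded persons_in persons_excluded
#> 1     complete_bp       3182                0        400                0
#> 2  height_present       3182              172        400                0
#> 3 growth_outliers       3010                3        400                0
#> 4     bp_outliers       3007                1        400                0
#> 5   min_occasions       3006                0        400                0
res$report
#>   age_group participants cases_fourth_2004 rate_fourth_2004 cases_aap_2017
#> 1       1-7          299                13            43.48             13
#> 2      8-12          264                 3            11.36              3
#> 3     13-17          237                 7            29.54              7
#>   rate_aap_2017 kappa kappa_ci_low kappa_ci_high     kappa_band pct_agreement
#> 1         43.48     1            1             1 almost_perfect           100
#> 2         11.36     1            1             1 almost_perfect           100
#> 3         29.54     1            1             1 almost_perfect           100
```

The attrition table mirrors the injected defect rates (5% missing heights,
0.1% implausible BP/weight entries); the planted categories are concordant
across guidelines by construction, hence κ = 1 here — use
`bp_model = "ambient"` for naturally discordant cohorts. Rates are cases
per person-year units at risk × 1000, rounded half-up:

```r
event_rate(1300, 218368)
#> [1] 5.95
cohens_kappa(40, 5, 5, 50)
#> Cohen's kappa agreement (2x2)
#>   cells: n11=40 n10=5 n01=5 n00=50 (N=100)
#>   kappa = 0.7980 (95% CI 0.6792-0.9167), SE 0.0606 [substantial]
#>   percent agreement = 90.00%
```

`res$annual` holds the calendar-year trend (plot with
`plot_annual_series`), and `res$pmca` the complexity levels:

```r
table(res$pmca$level)
#>     complex_cd non_complex_cd     without_cd
#>            104            152            144
```

A thin command-line front end wraps the same functions
(`inst/cli/pedhtn.R`; subcommands `simulate`, `qc`, `classify`, `agree`,
`rates`, `pmca`, `report`, `all`).

## Documentation

The methods vignette (`vignettes/pediatric-bp-surveillance.Rmd`) documents
the models, the interpretation choices (strict QC boundaries, occasion
counting, denominators), the synthetic generator's design and its limits,
and all numerical conventions.
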