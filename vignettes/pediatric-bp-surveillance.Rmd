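---
title: "Guideline-based pediatric BP surveillance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guideline-based pediatric BP surveillance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedhtn)
```

## The surveillance problem

Pediatric hypertension is defined against *normative* blood pressure: below
age 13 (2017 AAP) or 18 (2004 Fourth Report), a child's systolic and
diastolic readings are ranked within a reference distribution indexed by
sex, age, and height percentile, and categories are defined by percentile
cutoffs rather than fixed mmHg values. Routine outpatient vital-sign
records in EHR systems therefore cannot be screened with a single
threshold: each reading needs its own resolved cutoffs, and a diagnosis
needs repeated qualifying readings on separate occasions within one year of
age. `pedhtn` implements that workflow end to end — quality control,
threshold resolution under the 2004 Fourth Report and the 2017 AAP
guideline, person-year classification, rates, inter-guideline agreement,
medical-complexity covariates, and association analysis — as a table-driven
pipeline that works with any conforming reference tables.

## Normative models

**LMS z-scores.** Growth references are consumed in the LMS
parameterization: for a measurement $x$ with reference power $L$, median
$M$, and coefficient of variation $S$,

$$ z = \frac{(x/M)^L - 1}{L\,S} \quad (L \ne 0), \qquad
   z = \frac{\log(x/M)}{S} \quad (L = 0), $$

which is continuous in $L$ at 0 and strictly increasing in $x$. Height
percentile is the standard-normal CDF of $z$ and is the lookup key into the
BP reference tables. Between tabulated month rows, $L$, $M$, $S$ are each
interpolated linearly in age; this is simple, monotone on smooth
references, and matches what clinical calculators do. Ages outside the
reference span raise an error rather than extrapolating.

**Threshold resolution.** The guideline rule sets are resolved into a
numeric `ThresholdSet` (elevated and hypertension cutoffs for SBP and DBP)
per person-visit context:

| context | elevated | hypertension |
|---|---|---|
| Fourth Report, 1–17 y | min(90th pct, 120/80) | 95th pct + 5 mmHg |
| AAP, 1–12 y | min(90th pct, 120/80) | min(95th pct, 130/80) |
| AAP, 13–17 y | 120/80 (static) | 130/80 (static) |
| both, 18–20 y | 120/80 floor | 140/90 (adult rule) |

Three categories are used per guideline (normal, elevated/prehypertension,
hypertension); the AAP stage 1/stage 2 distinction is deliberately out of
scope. Two documented interpretation choices: the Fourth Report
hypertension rule is implemented as "95th percentile + 5 mmHg" (the
three-category collapse of its staging), and the adult diastolic cutoff is
90 mmHg (the alternative 89 that sometimes appears in secondary tables is
treated as a typo). Height percentiles outside the tabulated 5–95 grid
clamp to the boundary column; inside the grid, values are interpolated
linearly, and a lookup at a grid column returns the cell exactly.

The published reference tables are *not* bundled: the engine consumes any
delimited file matching the `read_bp_reference()` schema, enforcing on load
that values increase strictly in BP percentile and non-decrease in height
percentile. Synthetic tables with the same structure ship for tests.

## Quality control

Filters run in a fixed order with stage-by-stage attrition accounting:
complete SBP+DBP pair, height present, growth-outlier screen, BP
plausibility bounds, minimum separate occasions.

* **Growth screen:** height-for-age or weight-for-age $|z| > 6$ SD. The
  inequalities are strict — $z = \pm 6.0$ exactly is retained — and a
  small numeric tolerance ($10^{-7}$) keeps binary representation error
  from flipping boundary cases.
* **BP plausibility:** exclude SBP > 240 or < 60, DBP > 160 or < 30 mmHg;
  bounds are exclusive, so 240/160 and 60/30 are retained.
* **Occasions:** at least 3 visits on distinct calendar dates over the
  study period ("at least 1 day apart" read as distinct dates; a wider
  `min_gap` thins greedily).

The height filter defaults to per-visit exclusion, dropping a person only
when no visit survives; a stricter person-level mode is available because
the participant-level phrasing of typical cohort descriptions is ambiguous.
The three record-level filters are per-record predicates, so total
survivors are invariant to their ordering (tested on random cohorts); the
attrition report fixes the order above for comparability.

## Person-year classification

The unit of analysis is the person-year of age: $[k\text{-th birthday},
(k{+}1)\text{-th birthday})$, with age in completed years. Same-date repeat
readings collapse to one occasion (first-of-day by default; mean
available). Thresholds are resolved per visit from that visit's age and
height. A person-year is hypertensive when at least three SBP *or* at least
three DBP occasions meet the hypertension threshold; elevated by the same
rule against the elevated thresholds; SBP and DBP tallies are kept separate
and OR-ed, so a mixed 2+2 pattern does not qualify. Readings at
hypertension level also count toward the elevated tally (the thresholds are
nested), giving the monotonicity property that raising any reading never
lowers a category. Person-years with fewer than three occasions are
flagged ineligible: they can never be classified hypertensive or elevated,
but by default (`denominator = "any_obp"`) they stay in rate denominators,
which count every person-year with at least one measurement. The
alternative `eligible_only` restricts denominators (and the agreement
2×2) to person-years meeting the occasion rule; both are supported because
published person-year counts, percent agreement, and kappa are not always
mutually consistent under a single construction, and no attempt is made to
match any particular published kappa.

## Statistics

Rates are cases per participants at risk × 1000, rounded half-up to two
decimals; age strata default to 1–7, 8–12, 13–17, 18–20 years and are not
mutually exclusive. Annual rates use distinct persons with a visit in the
calendar year as the denominator and distinct persons whose hypertensive
person-year overlaps that year as the numerator.

Agreement between the guidelines dichotomizes each person-year as
hypertensive versus not, builds the 2×2 concordance table, and computes
Cohen's κ. No SE formula is mandated by convention in surveillance reports,
so the package uses the large-sample Fleiss–Cohen–Everitt asymptotic
variance; the test suite cross-checks it against a 10,000-replicate
multinomial bootstrap (they agree to a few percent at $N = 100$).
Interpretation bands follow the usual breaks (≤ 0.20 none, 0.21–0.40 fair,
0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1.00 almost perfect), with
the estimate rounded half-up to two decimals before banding so values
falling between printed bands land on a boundary.

Association analysis is an ordinary maximum-likelihood logistic regression
of hypertensive versus pooled elevated/normal person-years, fitted within
age strata, with Wald 95% intervals on the odds-ratio scale. Reports that
use matched ("conditional") designs do not always state their matching
structure; this package deliberately implements the unconditional
stratified fit and says so — if you need conditional ML on matched sets,
use a dedicated survival/clogit tool on the exported person-year table.
Complete separation is detected (unstable coefficient/SE) and reported as
an error naming the covariate rather than returning a meaningless interval.

BMI is weight/height², categorized against an LMS bmi-for-age reference at
the 5th/85th/95th percentile breaks (underweight < 5, overweight [85, 95),
obesity ≥ 95).

## Medical complexity (PMCA)

The conservative Pediatric Medical Complexity Algorithm is implemented as a
code-map-driven classifier: a condition (a map entry group keyed by body
system and its progressive/malignancy flags) qualifies when mapped ICD-9/10
codes appear on ≥ 2 distinct outpatient/ED encounter dates — two codes on
one date are treated as duplicate coding of a single encounter — or on ≥ 1
inpatient discharge, within the half-open window $[\text{index} - 365\text{
d}, \text{index})$. Complex chronic disease requires ≥ 2 body systems or a
progressive or malignant condition; exactly one system without flags is
non-complex chronic; otherwise without chronic disease. Matching is longest
prefix within ICD version; unmapped codes are ignored but tallied. The full
published PMCA code lists are a plug-in like the BP tables; a synthetic map
ships for tests. The index date defaults to the person's first outpatient
BP visit (configurable), since complexity is a baseline covariate for the
BP classification that follows.

## What the synthetic generator emulates — and what it does not

`gen_cohort()` produces visit panels with a persistent per-person height
and weight track (latent z-scores held fixed across visits), at least three
occasions per person-year on distinct uniform dates, planted person-year
categories at configurable prevalences, planted chronic conditions emitted
as qualifying encounter patterns, and defect injection (missing heights,
implausible BP and weight entries) at configurable rates. Ground truth is
recorded before defect injection.

Key generator choices:

* **Concordant planting.** Planted readings are placed relative to the
  thresholds of *both* guidelines — hypertensive above the larger
  hypertension cutoff plus a safety margin (default ± 2 mmHg), normal below
  the smaller elevated cutoff minus the margin — so the planted label is
  correct under either guideline and recovery can be asserted exactly.
  Elevated readings sit at the midpoint of the cross-guideline band, whose
  width with the synthetic tables can be under twice the margin; the
  midpoint keeps ≳ 1 mmHg of clearance on each side, which is ample
  relative to the ≤ 0.05 mmHg rounding of stored readings. Setting the
  margin to 0 enables deliberate boundary testing.
* **Ambient mode** draws readings from the normative Gaussian model with a
  persistent per-person BP offset instead of planting categories; it
  produces natural category spread and inter-guideline discordance, and is
  what the direction-of-reclassification checks use.
* **Synthetic references.** The growth reference uses $L = 1$ throughout
  (closed-form z-scores for hand-checkable tests) with monotone median
  curves; the BP tables come from a Gaussian normative model linear in age,
  sex, and height z. The default `"aap_dominant"` style keeps every
  resolved AAP hypertension threshold at or below its Fourth Report
  counterpart — verified over the whole grid at generation time — so the
  AAP-classifies-more-adolescents direction holds by construction.
* **Defaults as study conditions.** 500 persons observed two consecutive
  age-years in a ten-year window starting 2009; 3 + Poisson(1) occasions
  per person-year; hypertension/elevated prevalence 1%/2%; missing-height
  rate 5%; BP and growth outlier rates 0.1% (invalid vitals are rare in
  source systems, typically well under 0.1% of observations, while missing
  heights are common). These were chosen once as plausible outpatient-EHR
  magnitudes and are not tuned.

Passing recovery tests on this generator shows the *pipeline logic* is
correct — windowing, threshold resolution, counting rules, attrition
accounting — under known ground truth. It does not validate the published
reference tables themselves, measurement-device behavior, care-seeking
selection, within-day reading protocols, or real ICD coding practice; none
of those are modeled.

## Numerical choices

* Presentation rounding is half-up (`round_half_up()`), not R's default
  round-half-even, matching how rates and κ are conventionally printed;
  a $10^{-9}$ guard absorbs binary error in integer ratios.
* Strict exclusion boundaries carry a $10^{-7}$ z tolerance (above).
* Degenerate κ margins ($p_e = 1$) raise a typed error that still reports
  percent agreement; CI ends are truncated to $[-1, 1]$.
* glm convergence: relative log-likelihood change $< 10^{-8}$, ≤ 100
  iterations.
* All randomness flows from a single integer seed; generation is
  byte-reproducible.

## Problem sizes used in the checks

The bundled verification suite runs cohorts of 60–400 persons for
behavioral tests, 2000 persons × 3 seeds × 3 planted prevalences
(0.001/0.005/0.05) for rate-recovery calibration, a 10,000-replicate
bootstrap for the κ SE cross-check, and exhaustive person-year
classification against a brute-force oracle over all 2001 multisets of up
to five readings on a 3 × 3 BP grid. These sizes give 3-SE calibration
bands a useful width while keeping the full suite around a minute on one
CPU.

## Known limitations

* Real Fourth Report / AAP tables and PMCA v2.0 code lists must be
  supplied by the user in the documented schemas.
* Stage 1 vs stage 2 hypertension, ambulatory/home BP protocols, infant
  (< 1 y) references, and ICD-code-based case definitions are out of
  scope.
* The association model is unconditional logistic regression by age
  stratum; it is not a matched conditional analysis.
* Age is integer years attained at the visit date; sub-year age effects
  within a person-year are not modeled.
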