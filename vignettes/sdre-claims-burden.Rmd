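---
title: "Methods: phenotyping and burden analysis of severely drug-refractory epilepsy in claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping and burden analysis of severely drug-refractory epilepsy in claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Drug-refractory epilepsy is clinically defined by continued seizures despite
two adequate anticonvulsant trials; administrative claims carry no such
label, and no ICD-10 code marks refractoriness. What claims do record,
completely and longitudinally, is prescribing: repeated switches and
additions of anticonvulsants (AEDs) are the claims-visible signature of
uncontrolled epilepsy. This package operationalises *severe*
refractoriness as a treatment-pattern phenotype — at least four distinct
AED substances dispensed within a rolling 18-month window, on top of a
coded G40\* epilepsy diagnosis — and builds the full comparative analysis
around it: an age/sex-matched epilepsy-free cohort, per-period burden
summaries, survival, and direct costs, all from five delimited claims
tables.

## The phenotype, precisely

Let the insurant's prefix-matching dispensations (ATC `N03A`, 7-character
substance level, case-insensitive) have dates \(x_1, \dots, x_m\). For a
candidate date \(d\), the window count is

\[ c(d) \;=\; \#\{\text{substances } s : \exists\, x_j \in (d - w,\, d]
   \text{ with substance } s\}, \qquad w = 548 \text{ days}. \]

The index date is the earliest \(d\) in the identification interval
(2009-01-01 to 2010-12-31) with \(c(d) \ge k\), \(k = 4\). Only dispense
dates need be examined: \(c\) increases only there. Consequently the index
is the dispense date of the k-th substance of some qualifying window, and
three properties hold that the test suite checks against a brute-force
window enumeration: (i) oracle equivalence on arbitrary histories, (ii)
monotonicity — adding a dispensation can only advance the index — and
(iii) equivariance under shifting a history in time.

Decisions worth making explicit, because the informal definition
underdetermines them:

* **Window membership** requires a dispensation *inside* the window, not
  merely a first-ever dispensation inside it: a drug started long ago but
  still being refilled counts toward concurrent polytherapy. This is the
  literal reading of "four different AEDs in an 18-month period".
* The window is half-open, \((d - 548, d]\); 18 months is fixed at 548
  days. Both are `phenotype_config()` parameters.
* "Between 2009 and 2010" anchors the *index* (the fourth-substance date);
  earlier substances may precede 2009. The index is the anchored event
  because it starts the follow-up clock.
* The G40\* diagnosis may occur anywhere in the observation window: no
  temporal link between coding and prescribing is imposed.
* Substances are counted at the ATC 7-character level; benzodiazepines
  count only when N03A-coded (clonazepam `N03AE01` yes, lorazepam
  `N05BA06` never).
* Cases must be enrolled at the index date. Continuous-enrollment
  requirements over baseline and follow-up are *not* imposed; instead
  every proportion reports its per-period at-risk denominator, so
  alternative conventions can be recomputed from the output.

## Cohort time, denominators and conventions

The index anchors baseline \([d-365, d)\) and follow-up years
\([d + 365(y-1),\, d + 365y)\), \(y = 1,2,3\) — person-anchored 365-day
blocks, not calendar years. The cost module additionally offers a
calendar-year mode (baseline 2010, follow-up 2011–2013) because billing
data are naturally calendar-shaped; the person-anchored mode is primary.

A person is *at risk* in a period when alive and enrolled at its start;
exposure runs to the earliest of period end, death and disenrollment.
Every proportion uses the at-risk count as denominator, and numerators are
restricted to at-risk persons, so numerator ≤ denominator and deaths shrink
later denominators monotonically. Admissions belong to the period holding
their admit date even when the discharge crosses the boundary, and the
length of stay counts both boundary days (same-day admission = 1 day) —
whole-case accounting in the style of DRG billing. Quarter-resolution
records (outpatient diagnoses and contacts) are located by quarter
midpoint, the only defensible point estimate when billing collapses a
quarter.

Matching is exact on birth year and sex (an `age_tolerance` widens it for
thin strata), without replacement, from the pool of insurants with no
G40-prefixed code ever, alive and enrolled at the case's index date.
Controls inherit the case's index as pseudo-index — the published design
is silent on control time zero, but per-year control rates require one.
Each case samples its controls with an RNG sub-stream derived from the
master seed and the case id, so a fixed seed fixes the cohort and, while
pools are ample, one case's controls do not depend on which other cases
exist; cases compete for scarce controls in ascending id order and
shortfalls are recorded, never padded. Whether the historical match was
with or without replacement is unstated; without replacement is the
stricter choice and is what "each control used once" audits expect.

## Statistical kernel

The kernel is deliberately small and self-contained, so that every number
in the reports traces to a few inspectable lines; `survival::survfit` and
`stats::chisq.test` appear only as independent cross-checks in the tests.

* **Pearson chi-square, 2×2**: \(\sum (O-E)^2/E\), df = 1, two-sided
  p-value; no continuity correction by default (Yates optional); no
  multiple-testing adjustment anywhere, matching the explorative design.
  P-values are formatted to three significant digits with `<0.001` below
  that.
* **Kaplan–Meier**: standard product-limit with Greenwood variance;
  subjects censored exactly at an event time count as at risk for that
  time (events before censoring). Cumulative mortality at a horizon is
  1 − S at the largest event time not after the horizon; horizons beyond
  the observed range warn about extrapolation. Same-day deaths receive a
  half-day duration so durations stay positive.
* A two-sample log-rank test is included as an extra beyond the
  chi-square/KM core.

## What the synthetic generator emulates — and what it does not

`simulate_claims()` produces databases shaped like a 5%
population-representative statutory-insurance research sample over
2008–2013 (24 billing quarters), with ground-truth labels. Its defaults are
the study conditions of the published SDRE setting:

| Parameter | Default | Anchor |
|---|---|---|
| age/sex pyramid | German-like bands, mean age ≈ 43 | population representativeness |
| epilepsy prevalence | 0.008 | population prevalence of treated epilepsy |
| refractory fraction (`paper_like`) | 0.0240 | 769 cases per 4M insured |
| accrual gap mean / cap | 80 / 175 days | ≈ 212-day mean first-to-fourth latency, span < 548 d |
| post-index new-substance probability | 0.11 / quarter | ≈ 5.3 distinct AEDs over follow-up |
| case admission rate | 1.042 / person-year | 2,403 admissions / 769 / 3 years |
| control admission rate | 0.183 / person-year | 8,461 / 15,380 / 3 years |
| admission dispersion (gamma shape) | 0.8 cases / 0.25 controls | annual (42.7–55% vs 11.6–12.8%) and 3-year (73.9% vs 27.9%) any-admission shares |
| epilepsy fraction of case admissions | 0.417 | 1,002 / 2,403 |
| case mortality hazard | 0.0812 yr⁻¹ (year 1), 0.0348 yr⁻¹ after | 7.8% first-year, 14% three-year risk |
| background hazard | 0.00707 yr⁻¹ | 2.1% three-year control risk |
| length of stay | lognormal(log 7, 0.8) | ≈ 9.7-day mean stay |
| cost distributions | lognormal per component | ≈ €12.9–14.6k direct cost/person-year, 37–42% inpatient |

Admission counts use a per-person gamma frailty because a pure Poisson
process cannot match the printed mean rate and the printed any-admission
proportions simultaneously; the frailty shape is derived analytically from
those proportions. Mortality is piecewise-constant-hazard from the index
for cases and exponential from enrollment for everyone else; coverage ends
at death. Drug histories are quarterly stay/add processes over a
14-substance N03A pool with realistic market shares; refractory insurants
accrue four distinct substances within a guaranteed sub-548-day span ending
in the identification window, which makes the phenotype *exactly*
recoverable at the default cap of three lifetime substances for
non-refractory epileptics (raise `max_nonrefractory_substances` to study
overlapping regimes; sensitivity and specificity stay ≥ 0.95 at the default
separation). Comorbidity diagnoses are independent per-year Bernoulli draws
per ICD block with case/control probabilities.

Deliberate simplifications — and therefore things a passing test suite
does **not** establish about real claims: no within-patient correlation of
comorbidities, no seasonality, no coding error or miscoding, no
age-dependent mortality or admission risk, no treatment discontinuation for
adverse events, no insurance churn by default (an `enrollment_gap_prob`
exists but no published value constrains it), and no realistic DRG
catalogue — admission costs are draws, not grouped tariffs, exactly as the
analysis treats cost as a given per admission.

## Code sets

The comorbidity comparison needs ICD code sets, only some of which the
source setting specifies (F06, F45, F07, S00–S09, T08–T14, S80–S89,
S90–S99). The remainder are explicit assumptions shipped in an editable
config file (`inst/extdata/codesets.cfg`): depression F32–F33, vascular
disorders I60–I79 + G45, gastrointestinal K20–K93, hypertension I10–I15.
Ranges match on the first three characters, prefixes by prefix.

## Problem sizes and numerical choices

The test suite and the acceptance script are sized to run comfortably on a
single CPU: fuzzing uses 1,000 prescription histories (≤ 50 dispensations)
and 500 survival samples (n ≤ 32); parameter-recovery simulations use
20,000 insurants with an enriched case pool (~500–1,000 cases), since the
estimated quantities are rates and means whose expectations do not depend
on prevalence; the acceptance pipeline uses 40,000 insurants. Chi-square
equality to the closed form is asserted at 1e-9; survival equality to the
brute-force loop at 1e-12; cost conservation to the cent (components are
rounded to cents at source, the total is their exact sum). Ties in
substance accrual break by ATC code order; matching pools are sorted by
insurant id before the seeded permutation so results are independent of
table order.

## Limitations

A treatment-based phenotype cannot distinguish refractoriness from
switching for adverse events; the matched design controls age and sex but
not comorbidity (no propensity matching, by design); epilepsy-specific
attribution rests entirely on the primary inpatient ICD; and the synthetic
data, however calibrated, cannot validate the phenotype against clinical
truth — only against its own generating labels. Control costs are computed
for completeness but no published control cost breakdown exists to compare
them to, so they are flagged non-comparable.
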