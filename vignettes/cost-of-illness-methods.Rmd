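---
title: "Methods: severity-stratified cost-of-illness modelling for atopic dermatitis"
author: "adcoi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity-stratified cost-of-illness modelling for atopic dermatitis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcoi)
```

## The model

adcoi estimates the annual national economic burden of atopic dermatitis
(AD) for Romania, reference year 2022, from a broad perspective. The burden
is a sum over two population segments (adults, 20+ years; pediatric, <20
years, reported by caregivers), three self-rated severity strata
(mild/moderate/severe) and six cost components:

* **direct medical**: treatment, medical services (adults only; the
  pediatric survey did not collect it), and inpatient hospitalization;
* **direct non-medical**: associated out-of-pocket costs (transport,
  accommodation, other);
* **indirect**: productivity losses from absenteeism, valued by the
  human-capital approach.

The first two bottom-up components multiply a per-patient survey mean
$\bar c_{s,k}$ (severity $s$, category $k$, EUR/year) by the extrapolated
national case count $N_s$:

$$ C_{s,k} = \bar c_{s,k}\, N_s, \qquad
   N_s = N \cdot \frac{n_s}{n_{\text{survey}}}, $$

where $N$ is the GBD 2021 crude count for the segment on the chosen basis
(prevalence or incidence) and $n_s$ the integer survey severity count
(141/368/113 of 622 adults; 22/21/14 of 57 caregivers). Hospitalization is
top-down: the 1,209 annual AD discharges are split between segments in
proportion to the GBD counts, then across severities by the survey
fractions, and each (unrounded) count is costed as
$\text{ALOS} \times \text{tariff/day} / \text{fx}$ (7.95 days and 1,094
RON/day for adults; 4.44 days and 1,012 RON/day for pediatric patients).
Productivity is hybrid: per-severity full-time and part-time worker counts
(case counts times survey employment shares) times mean missed days times a
gross daily wage, $6{,}126 \times 12 / 251$ RON for full-time and half that
for part-time work. Four scenarios cross the epidemiological basis with the
treatment-cost source: survey-reported means versus the national average
prescription value (40.4 RON/year).

Per-patient averages divide totals by **all** cases in the stratum, not
only cost-incurring ones; that is how the published averages are
constructed.

## Numerical conventions

* **Rounding.** Counts are rounded half-up, and only at the final reporting
  step; every chained computation (segment hospitalization shares, severity
  splits) uses unrounded intermediates. This is what makes the published
  hospitalization triples (93/243/75, 108/281/86, 308/294/196, 283/270/180)
  reproduce exactly. Independent per-stratum rounding means stratum sums may
  differ from the national total by up to half a count per stratum; the
  unrounded strata always sum to the total exactly. One published cell
  (adult prevalence severe, 9,593) sits on the other side of the half-count
  boundary than integer inputs imply ($52{,}801 \times 113/622 =
  9{,}592.46$); GBD point estimates are not integers, and an unrounded 20+
  count of $\approx 52{,}801.2$ reproduces it. The package takes the printed
  integer inputs at face value and reports 9,592.
* **Currency.** A single RON/EUR scalar, default 4.9315 (2022 annual
  average), converts all RON-denominated unit costs. The source material's
  own conversions imply two slightly different rates (its wage pair implies
  4.9313, its hospital tariff pair 4.976); we use one configurable scalar
  rather than averaging, and totals are insensitive at the 0.1% level.
* **Hospital tariff basis.** The 1,094/1,012 RON figures are treated as
  per-day tariffs: combined with the ALOS they reproduce the published
  hospitalization cost cells, whereas a per-admission reading is roughly
  an ALOS-factor too small. `unit_costs(hospital_cost_basis = "per_stay")`
  preserves the literal per-admission reading for sensitivity use.
* **Degenerate inputs.** Empty severity strata yield flagged zero means (a
  warning, not an abort); zero discharges or zero case counts propagate to
  zero totals; a zero-variance imputation predictor is dropped with a
  warning.

## The synthetic survey generator

No respondent-level data were deposited, so the package ships a seeded
generator (`generate_cohort()`) that emulates the two cohorts' *published
margins* and leaves everything else as explicit, documented choices:

* **Severity margins are exact**, never sampled: generation is stratified.
* **Costs** are log-normal within stratum (non-negative, right-skewed, the
  standard shape for expenditure data), parameterized by the target mean
  and a coefficient of variation (default 1.0 — the study published no
  variances). With calibration on (default), draws are rescaled
  multiplicatively so each per-severity category mean matches its target
  *exactly*; the published input averages are therefore recovered to 1e-9
  by `severity_averages()`.
* **Missed days** are gamma draws calibrated the same way for the full-time
  and part-time classes.
* **EQ-5D-5L states** are drawn dimension-wise: the level-1 probability per
  age band matches the published dichotomized frequencies; the residual
  "problems" mass is split over levels 2–5 as (0.55, 0.30, 0.12, 0.03), a
  choice (the study published only the dichotomy). **EQ-VAS** values are
  beta draws scaled to 0–100 and calibrated to the published per-band
  mean/SD by alternating exact-moment standardization with clipping to the
  scale bounds, which converges because the published moments are well
  inside the feasible region.
* **Employment** is a per-severity simplex. The published full/part-time
  national worker counts imply overlapping shares (full-time plus part-time
  exceeding 1 for some strata), which no simplex can generate; the
  generator uses a coherent mix, while the extrapolation layer takes the
  back-solved shares as data (below).
* **MNAR mechanism** (`inject_mnar()`): the deletion probability of a
  treatment cost is logistic in the record's own standardized cost, with
  the intercept solved so the expected missing fraction hits the target
  rate. Default rate 0.15 and slope 1 for the adult cohort — the study
  reported MNAR missingness in this column but not its extent, so both are
  generator parameters, not claims about the study. Setting the slope to 0
  reduces the mechanism to MCAR, which the test suite exploits.

What passing tests on these data do **not** show: anything about convenience
sampling bias, recall error, or the true joint distribution of costs and
severity in Romanian AD patients. The generator reproduces published
marginal moments, nothing more.

## Missingness diagnosis and imputation

`missingness_report()` combines a Little-type MCAR chi-square with a
logistic regression of the missingness indicator on observed covariates.
The chi-square compares each missingness pattern's observed-variable means
against maximum-likelihood estimates of the mean and covariance obtained by
an EM algorithm over patterns (ML `1/n` scaling), with
$\sum_j p_j - p$ degrees of freedom. Simulation in the test suite puts its
type-I error at $\alpha = 0.05$ within three binomial standard errors over
1,000 replicates. The conclusion rule: MCAR if neither instrument rejects
at $\alpha = 0.05$; MAR if any covariate coefficient is significant; MNAR
assumed otherwise (dependence on the unobserved value is not directly
testable from observed data).

`impute_treatment()` is chained-equations imputation with predictive mean
matching: Bayesian linear model per incomplete column (posterior draws of
the residual variance and coefficients), donors drawn uniformly from the
`k = 5` observed rows with closest predicted means, `m = 5` completed
datasets over 10 sweeps, point value the across-imputation mean (downstream
costing consumes one completed table). The study named its tooling but not
its settings; these are conventional defaults, all configurable. Note that
PMM, like any MAR-based method, understates the mean under a truly MNAR
mechanism — visible in the stage-2 driver, where the imputed treatment
means sit below the calibrated complete-data means. The study did not state
how it accommodated MNAR after ruling out MCAR/MAR; we do not pretend to
recover its unstated adjustment, and the costing engine takes the published
averages as inputs for the reproduction of record.

## Productivity calibration is fixture data

The published per-severity worker counts and productivity totals cannot be
re-derived from any published survey margin. The package therefore ships
`inst/extdata/productivity_calibration_synthetic.csv` — employment shares
and mean missed days back-solved from the published prevalence-side figures
(e.g. moderate full-time: 17,125 workers, 0.9027 days/year) — labelled
synthetic, and exposes the formulas with these as inputs. The published
caregiver *incidence* productivity components are internally inconsistent
with the stated formula (the part-time figure implies more missed days than
there are working days); the prevalence side, which is self-consistent, is
what the calibration reproduces.

## EQ-5D-5L scoring

`eq5d_index()` applies additive value-set scoring: utility
$= 1 - \sum_d \delta_{d,\ell_d}$, anchored at 1 for state 11111.
No national Romanian 5L tariff exists and the source analysis never named
one, so the packaged value set is **synthetic**: 20 decrements, constructed
to be level-monotone with floor $-0.025$ and with state 45555 scoring
exactly 0.017, so the extreme utilities reported for the study population
are representable. Published utility ranges are treated as fixtures for
this set, not as reproduction targets; any real tariff CSV with columns
`dimension, level, decrement` can be swapped in via `read_value_set()`.
Caregiver-completed pediatric states are scored with the same set.
Dichotomization groups level 1 as "no problems" and levels 2–5 as
"problems"; EQ-VAS summaries use the sample SD and type-7 (linear
interpolation) percentiles.

## Problem sizes and test design

The test suite and the acceptance script run at the study's own scale —
cohorts of 622 and 57, national counts in the tens of thousands — which is
desk-scale arithmetic. The simulation-based checks use 1,000 replicates of
n = 150 for the MCAR type-I calibration, 20 replicates of n = 2,000 for
its power under value-dependent deletion, and n = 2,000 for imputation
parameter recovery under MCAR (bias under two standard errors of the
complete-data mean). These sizes give stable verdicts for the properties
checked while keeping the whole suite under a minute of simulation time.

## Known limitations

* The engine reproduces the published *prevalence-side* totals to better
  than 0.1%; small residual gaps trace to the published inputs' printed
  rounding (integer-printed pediatric cost means carry up to 0.56%
  half-ulp error) and to the one case-count cell discussed above.
* Incidence-based caregiver productivity follows the package's coherent
  formula, not the source's internally inconsistent printed components, so
  the pediatric incidence grand total is materially lower than the
  published one — deliberately.
* No uncertainty propagation: GBD inputs are crude point counts and the
  analysis is deterministic given its inputs. Probabilistic sensitivity
  analysis is a natural extension, not implemented here.
* Presenteeism, friction costing, discounting and controlled/uncontrolled
  disease distinctions are out of scope.
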