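---
title: "Estimating water turnover from survey aggregates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating water turnover from survey aggregates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtbudget)
```

## The problem

Water turnover (WT) — the total daily flux of water through the body — is the
gold-standard quantity for setting water requirements, but measuring it with
isotope dilution (doubly labelled water, DLW) is too expensive for national
surveillance. The international DLW database group published a multiple
regression equation (R² = 0.471) that predicts WT from anthropometric,
lifestyle and environmental covariates. `wtbudget` applies that equation to
group-aggregate national survey tables — the packaged default is the 2016
National Health and Nutrition Survey, Japan (NHNS-J; 10,546 men and 12,355
women aged 15–80 in 14 sex-by-age groups) — partitions the predicted WT into
its physiological sources, models its dose–response against age, and
quantifies how much one-day dietary records (DRs) underestimate water
consumption relative to the equation.

## The prediction equation

For one person (or one group-mean row),

$$WT = \beta_0 + \beta_1\,PAL + \beta_2\,W + \beta_3\,\text{sex} +
\beta_4\,RH + \beta_5\,\text{athlete} + \beta_6\,HDI + \beta_7\,\text{alt} +
\beta_8\,\text{age}^2 + \beta_9\,\text{age} + \beta_{10}\,T^2 +
\beta_{11}\,T$$

with sex coded 1 for men and 0 for women, athlete status 1/0, Human
Development Index class 0/1/2 for high/middle/low, relative humidity in
percent, altitude in metres, temperature in °C, and the published
coefficients as defaults (`wt_coefficients()`). Coefficients are data, not
code: any β can be overridden through the run configuration, which is how
sensitivity analyses (alternative PAL sources, perturbed coefficients) are
expressed. The age response is concave with its maximum at
$-\beta_9/2\beta_8 \approx 35.1$ years; the temperature response is convex
with minimum near 5.3 °C.

The equation was calibrated on adults ≥ 18 years. The survey's youngest
bracket is 15–19, so the package follows the published practice of applying
the equation there anyway, attaching an explicit flag
(`age_below_calibration_range`) rather than refusing or silently accepting.

## Energy-side inputs

The survey collects no physical-activity or TEE data, so PAL is approximated
by calibrated energy intake over predicted basal metabolic rate:

* **Calibration.** Reported DR energy intake is multiplied by 1.09,
  compensating the ≈ 9% under-reporting of DRs against DLW-measured
  expenditure in Japanese adults.
* **pBMR.** The Ganpule anthropometric equation for Japanese adults,
  $pBMR(\mathrm{MJ/d}) = 0.1238 + 0.0481W + 0.0234H - 0.0138A - 0.5473S$
  (S = 1 men, 2 women). Being linear, the pBMR of group means equals the
  group-mean pBMR, which is what makes aggregate-level reproduction exact up
  to the unknown within-bracket mean ages (about 1%).
* **Food quotient.** Energy-weighted mean of the macronutrient RQ
  coefficients (0.8 protein, 0.7 fat, 1.0 carbohydrate) with Atwater 4/9/4
  kcal/g. Gram-weighting was rejected: it yields ≈ 0.92 for the youngest
  male group where the published table prints 0.89.
* **CO₂ production.** $rCO_2 = EI_{cal}/(1.106 + 3.94/FQ)$, in L/day, with
  calibrated intake in kcal/day (kJ → kcal via the survey's own factor
  0.239, configurable).
* **Alcohol share.** The survey tables print no alcohol intake. By default
  the alcohol energy percentage is the non-negative residual of reported
  energy not covered by protein, fat and carbohydrate; this convention
  reproduces the published metabolic-water column to within a few ml/day,
  while assuming zero alcohol does not. An explicit `alcohol_g` column
  overrides it. Energy percentages are computed on *reported* intake but the
  metabolic-water formula multiplies them by *calibrated* intake — again the
  combination that reproduces the published column.

## The water partition

$$W_{met} = EI_{cal}\tfrac{1}{100000}\,[0.119\,\%fat + 0.103\,\%pro +
0.150\,\%carb + 0.168\,\%alc]$$
$$W_{res} = [AH/1000] \times 0.035\,rCO_2 \qquad
W_{trans} = [0.18\,AH/21.7] \times c \times BSA \times 1.44$$
$$W_{pre} = WT - [W_{met} + W_{res} + W_{trans}]$$

with absolute humidity AH in g/m³, DuBois body surface area
$0.007184\,W^{0.425}H^{0.725}$, and clothing coefficient $c = 0.5$ (clothing
halves transdermal exchange). The bracketed products are litres per day and
are returned ×1000 as ml/day — the only consistent unit reading: it
reproduces every published component cell (e.g. 355/124/76 ml/day for the
youngest male group). Conservation, $WT = W_{met}+W_{res}+W_{trans}+W_{pre}$,
holds to machine precision by construction and is asserted in the tests.

Absolute humidity defaults to the published survey value 7.45 g/m³; setting
the override to `NULL` derives it from temperature and relative humidity
with the Tetens saturation formula, which gives 7.43 g/m³ at (10.9 °C,
74.7%). The saturation formula behind the published value is not stated
anywhere we could find; third-digit differences are attributable to that
choice, which is why the injectable override exists.

## Group-aggregate conventions

Group rows carry no mean age, so the bracket midpoint is used: 17.5, 25, 35,
45, 55, 65, and 75 for the open ≥ 70 bracket (configurable
`open_bracket_age`; 75 is the midpoint of 70–80, the survey's age range).
Derived quantities (calibrated intake, pBMR, PAL) are recomputed from the
raw group means rather than read from the published derived columns: the
published columns are rounded, and recomputation reproduces the published
WT means more faithfully (both 40–49 means exactly, all closed brackets
within 0.5%). Open brackets carry an extra ≈ 1% uncertainty because the true
mean age of a 70–80 group is below its midpoint.

## Dose–response modelling

The relationship between water consumption and age is modelled with a
restricted cubic spline with three knots at ages 18, 48 and 77 (the 5th,
50th and 95th percentiles of the survey age distribution). With three knots
the design has one linear and one non-linear column; the curve is cubic
between the boundary knots and exactly linear outside them. Non-linearity is
a 1-df test that the non-linear coefficient vanishes. The primary test is
Wald with the large-sample χ²(1) reference; a likelihood-ratio variant
comparing the spline with the nested linear model is provided as a
cross-check, since the two are asymptotically equivalent and the choice is
not decidable from the published description. Group-aggregate fits are
weighted by group size to approximate the individual-level fit; individual
records are fitted unweighted. The linear-trend test is the t-test of the
age coefficient in a (weighted) linear regression.

Numerical edge cases: an exactly collinear design is a hard error; a perfect
fit (zero residual variance) makes the trend t-statistic 0/0, which is
resolved by the slope's magnitude (zero slope → p = 1, nonzero → p → 0);
the Wald statistic is defined as 0 when the non-linear coefficient is
exactly zero with nonsingular covariance.

## Dietary-record comparison

DR-based pre-formed water is beverage fluid plus 69% of food weight (the
mean water fraction of food in comparable record studies). Differences are
reported absolutely and relatively, with the *equation-based* value as
denominator — the convention under which the youngest male group shows
−1087 ml/day = −39.7%. In the aggregate tables the published beverage-fluid
column already equals the DR pre-formed value in every group, so the
group-level pipeline consumes it directly; the 69% rule is applied per
record on individual-level data (treating beverage weight as 1 g/ml). How
the published aggregate fluid column relates to the combined food-and-
beverage weight column is underdetermined from the published tables, so both
pathways are exposed and neither is guessed to be the published computation.

Two published absolute-difference cells (men 50–59, women 60–69) sit 1 ml
away from the printed-column arithmetic — they were evidently computed on
unrounded means. The regression tests assert exactness where the printed
columns are exact and ±1 ml elsewhere.

## The synthetic survey generator

Survey microdata are not public, so `generate_individuals()` produces
individual-level records whose group aggregates match configurable targets
(defaults: the packaged 2016 aggregates). Per group: age uniform within the
bracket; height and weight from a truncated bivariate normal (correlation
0.4 — unstated in any source; it affects nothing downstream because the
equations use weight and height separately); macronutrients and food weight
from independent truncated normals (truncated at 0 and mean ± 4 SD — the
minimal assumption when only means and SDs are published, and the truncation
guarantees positivity); alcohol from the group's residual energy share; and
reported energy rebuilt as 4P + 9F + 4C + 7A kcal times a multiplicative
noise term with CV 3%, so energy accounting stays internally consistent.
Sampling is inverse-CDF on a pinned generator (Mersenne-Twister, inversion),
so output is byte-identical for a fixed seed across platforms.

What the generator does *not* emulate: survey sampling design and household
clustering, seasonal variation, within-person day-to-day intake variation,
and any correlation between intake and body size (macronutrients are drawn
independently of weight). Passing end-to-end tests on synthetic data
therefore demonstrates that the pipeline machinery is correct and that the
published group-level *shapes* (female reverse-U, male late-age decline)
follow from the published group targets — not that the generator reproduces
real microdata.

One subtlety discovered while building the negative control: an age-flat
population (identical anthropometrics and intakes in every bracket) still
produces a genuinely non-linear WT–age truth, because the equation itself is
quadratic in age. A proper null for the non-linearity test therefore also
sets $\beta_8 = 0$ through the coefficient-override mechanism; the test
suite does exactly that.

## Problem sizes and runtimes

The default synthetic survey (22,901 records) generates and flows through
the full pipeline in well under a second. The test suite's operating-
characteristic simulations use 1000 replicates of n = 200 for the type-I
error of the non-linearity test (observed rate ≈ 0.05 under the χ²(1)
reference, consistent with its large-sample justification) and 200-replicate
scaled versions for the routine suite; these sizes give Monte-Carlo standard
errors comfortably inside the asserted bands.

## Known limitations

* Published confidence intervals for the group WT distribution cannot be
  reproduced from aggregates — they require individual-level variance — and
  are out of scope.
* The open-bracket (≥ 70) estimates inherit the midpoint-age convention and
  are accurate only to ≈ 1–1.5%.
* The equation's own prediction error (R² = 0.471) is metadata; no
  uncertainty propagation from it is attempted.
* The package deliberately has no shell executable: it is an analysis
  library, and `run_pipeline()` plus the scripts shipped in the repository
  are its operational surface.
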