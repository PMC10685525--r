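# wtbudget

Water-turnover estimation and water-budget partitioning from national
nutrition survey data.

## What it does, and for whom

Human water requirements are usually set from water turnover (WT) — the
total daily water flux through the body — which is gold-standard measured
with doubly labelled water (DLW). Because DLW is far too expensive for
surveillance, the international DLW database group published a regression
equation predicting WT from anthropometric, lifestyle and environmental
covariates. `wtbudget` is for nutrition epidemiologists who want to apply
that equation to survey tables: it takes group-aggregate rows (sex ×
age-bracket means of height, weight, energy and macronutrient intakes, food
and beverage weights) or individual records with the same fields, and

1. derives the energy-side inputs — calibrated energy intake (×1.09 for
   dietary-record under-reporting), predicted basal metabolic rate (Ganpule
   equation), physical activity level PAL = EI<sub>cal</sub>/pBMR, food
   quotient, CO₂ production, DuBois body surface area;
2. evaluates the WT prediction equation

   WT = β₀ + β₁·PAL + β₂·weight + β₃·sex + β₄·RH + β₅·athlete + β₆·HDI +
   β₇·altitude + β₈·age² + β₉·age + β₁₀·T² + β₁₁·T  (ml/day)

   and partitions WT into metabolic water (macronutrient oxidation),
   respiratory and transcutaneous water (atmospheric uptake), and
   pre-formed water (food and drink) by conservation:
   W<sub>pre</sub> = WT − [W<sub>met</sub> + W<sub>res</sub> + W<sub>trans</sub>];
3. models the dose–response of water consumption against age with a
   three-knot restricted cubic spline (knots 18/48/77 y) with Wald and
   likelihood-ratio non-linearity tests and weighted linear-trend tests;
4. quantifies how much dietary records underestimate pre-formed water
   relative to the equation, per group and as an age trend;
5. generates synthetic individual-level survey records whose group
   aggregates match configurable targets, so the full pipeline can be
   exercised without microdata access.

The 2016 National Health and Nutrition Survey, Japan (NHNS-J) group
aggregates ship as the packaged default fixture, together with the published
group-level water-budget distribution used by the regression tests.

## Worked example

```r
library(wtbudget)
res <- run_pipeline(nhns_groups())   # default config = the 2016 survey run
publication_view(res$budget)
```

```
    sex age_label    n  pal   wt w_met w_res w_trans w_pre wt_per_kg
   male     15-19  559 1.78 3299   357   124      76  2742     54.61
   male     20-29  710 1.48 3158   311   108      80  2660     46.72
   male     30-39 1207 1.48 3216   309   107      81  2720     46.48
   male     40-49 1581 1.52 3243   314   108      81  2739     45.75
   male     50-59 1486 1.59 3202   319   110      80  2693     45.94
   male     60-69 2307 1.70 3099   321   111      78  2589     46.52
   male      >=70 2696 1.72 2800   296   103      74  2327     45.45
 female     15-19  491 1.66 2649   259    90      66  2235     52.88
 female     20-29  779 1.50 2599   238    83      68  2210     48.85
 female     30-39 1350 1.60 2745   248    86      68  2343     51.22
 female     40-49 1819 1.60 2739   246    85      69  2339     49.36
 female     50-59 1777 1.71 2751   253    88      69  2342     49.83
 female     60-69 2641 1.85 2702   257    89      67  2289     50.13
 female      >=70 3498 1.94 2506   244    85      64  2112     49.62
```

Each row is one survey group: predicted water turnover `wt` and its
partition (all ml/day), derived PAL, and WT per kg body weight. The 40–49
groups reproduce the published means (3243 and 2739 ml/day) exactly after
rounding, and every closed bracket sits within 0.5% of the published value;
per-kg WT stays inside the published 45–56 ml/day band.

The comparison stage shows the dietary-record shortfall, e.g. for women:

```r
res$comparison[res$comparison$sex == "female",
               c("age_label", "preformed_equation", "preformed_dr", "diff_rel")]
```

```
 age_label preformed_equation preformed_dr  diff_rel
     15-19           2234.644         1299 -41.86993
     20-29           2209.742         1312 -40.62657
     30-39           2342.958         1443 -38.41119
     40-49           2338.864         1494 -36.12283
     50-59           2341.554         1620 -30.81517
     60-69           2289.482         1680 -26.62097
      >=70           2112.166         1564 -25.95278
```

Records capture only 58–74% of the equation-based pre-formed water, and the
underestimation shrinks with age (`res$trend`: slope ≈ +0.32 %/y for women,
+0.35 %/y for men, both p < 0.001). Spline fits live in `res$splines`; the
female WT–age curve rejects linearity (reverse-U shape) while the male curve
declines after age 50.

All analysis constants — calibration factor, kJ→kcal factor, environment,
clothing coefficient, food water fraction, bracket midpoints, equation
coefficients, PAL source — live in one run configuration
(`default_run_config()`, or a YAML/JSON file via `read_run_config()`), so
sensitivity analyses are config changes, not code changes.

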