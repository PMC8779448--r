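# gwgscreen

Antenatal weight-gain screening: weekly reference ranges, referral rules,
and their diagnostic performance.

## The problem

Clinical guidelines recommend that pregnant women gaining weight outside the
Institute of Medicine (IOM, 2009) recommendations be referred to a dietitian,
but referral pathways need a concrete, implementable trigger. A
practice-informed rule is: refer when a woman's cumulative gestational weight
gain (GWG) at an antenatal visit is more than 2 kg (or 5 kg) below the
minimum, or above the maximum, of her expected range — possibly requiring two
consecutive positive visits. `gwgscreen` is for maternity-service researchers
and biostatisticians who want to evaluate such rules: it models the expected
weekly range, applies the rules to longitudinal cohort data, and estimates
how well each rule predicts total GWG outside recommendations at 36 weeks.

## The model

**Reference ranges.** For pre-pregnancy BMI category *c* (WHO classes:
underweight < 18.5, normal 18.5–<25, overweight 25–<30, obese ≥ 30 kg/m²)
the IOM total-gain recommendation is an interval
[T<sub>min</sub>, T<sub>max</sub>] (e.g. 11.5–16 kg for normal). With a
first-trimester allowance [f<sub>min</sub>, f<sub>max</sub>] = [0.5, 2] kg
anchored at 13 weeks, the expected cumulative gain range at gestational week
*w* ∈ [13, 40] is linear in *w*:

    bound(w) = f + (w − 13)/27 · (T − f)

applied independently to the minimum and maximum. Both anchors are
configurable.

**Screening rule.** At a visit in week *w*, with margin *m* ∈ {2, 5} kg, the
test is positive iff gain < min(w) − m or gain > max(w) + m (strict
inequalities; equality with the widened bound is still "within"). A
consecutive-visit rule is the AND of two successive visits. The reference
standard is the same screen applied at the 36-week visit, at the same margin.

**Performance.** From the 2×2 table of test vs outcome: sensitivity
Se = tp/(tp+fn), specificity Sp = tn/(fp+tn), LR+ = Se/(1−Sp),
LR− = (1−Se)/Sp. Default 95% CIs are Wald intervals for Se/Sp and symmetric
delta-method intervals on the natural scale for the LRs (a log-scale /
Clopper–Pearson alternative is available).

**Synthetic cohorts.** `simulate_cohort()` generates WATCH-like cohorts
(n = 131, BMI mix 7/68/29/27, visits ≈ 19/24/30/36 weeks) from latent linear
gain trajectories a + r·(w − 13) with per-category bivariate-normal (a, r),
gestational-age jitter, scale noise, optional self-report error in the
pre-pregnancy weight, and known ground truth. An independent Monte Carlo
oracle (`oracle_performance()`) gives each rule's true operating
characteristics under the generative model.

## Worked example

```r
library(gwgscreen)

weekly_range(24, "normal")
#>   bmi_category  week min_kg max_kg
#> 1 normal          24   4.98   7.70

sim     <- simulate_cohort(sim_config(n_participants = 131,
                                      quota_exact = TRUE, seed = 2006))
screens <- screen_cohort(sim$cohort)
count_positives(screens, 24, 2)
#> [1] 68

evaluate_screens(screens)[, c("rule", "margin_kg", "sensitivity",
                              "specificity", "lr_pos", "lr_neg")]
#>   rule  margin_kg sensitivity specificity lr_pos lr_neg
#> 1 19            2        0.83        0.75   3.26   0.23
#> 2 24            2        0.91        0.85   6.07   0.11
#> 3 30            2        0.97        0.94  16.23   0.03
#> 4 19            5        0.42        0.93   6.45   0.62
#> 5 24            5        0.68        0.97  20.48   0.34
#> 6 30            5        0.82        0.98  37.54   0.18
#> 7 19+24         2        0.81        0.87   6.05   0.22
#> 8 24+30         2        0.91        0.96  20.24   0.10
```

A woman whose 24-week gain sits more than 2 kg outside the 4.98–7.70 kg
normal-category range tests positive; in this simulated cohort 68 of 131
women would qualify for referral at 24 weeks, and that rule detects 91% of
those who end up outside recommendations at 36 weeks while clearing 85% of
those who do not. Requiring two consecutive positives (rows `19+24`,
`24+30`) trades sensitivity for specificity, i.e. fewer unnecessary
referrals at the cost of missed women.

The `analysis/` directory holds the same workflow as numbered scripts
(`01_reference_table.R` … `04_evaluate_rules.R`), each writing its tables
under `results/`.

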