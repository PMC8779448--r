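---
title: "Evaluating gestational weight-gain referral rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating gestational weight-gain referral rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgscreen)
```

`gwgscreen` evaluates a simple, practice-informed antenatal referral rule:
flag a woman for dietetic referral when her cumulative gestational weight
gain (GWG) at a visit lies more than 2 kg (or 5 kg) outside the expected
range for her pre-pregnancy BMI category. This vignette is the package's
account of the underlying model, its assumptions, the choices that were
genuinely open, and what the synthetic-cohort tests do and do not
demonstrate.

## The weekly reference model

The IOM (2009) recommendations specify a *total*-pregnancy gain interval per
WHO BMI category: 12.5–18 kg (underweight, BMI < 18.5), 11.5–16 kg (normal,
18.5 to < 25), 7–11.5 kg (overweight, 25 to < 30) and 5–9 kg (obese,
BMI ≥ 30; obesity grades are not subdivided). Category boundaries are
half-open with the boundary value on the heavier side, so BMI 25 is
overweight and BMI 30 is obese.

To screen at an arbitrary visit these totals must become weekly ranges. The
package spreads each bound linearly from a first-trimester allowance
anchored at 13 weeks to the total at 40 weeks:

$$\mathrm{bound}(w) = f + \frac{w - 13}{27}\,(T - f), \qquad w \in [13, 40],$$

with the allowance $[f_{\min}, f_{\max}] = [0.5, 2]$ kg by default — the IOM
working assumption for first-trimester gain. The model is deliberately
undefined before 13 weeks: first-trimester gain dynamics (and losses from
nausea) are outside its scope. Two design points were open:

* **The week-13 anchor.** Whether a weekly-range implementation anchors the
  second trimester at the first-trimester allowance or at zero gain is a
  genuine modelling fork; the anchor is therefore a parameter of
  `iom_targets()`, and setting `first_trimester = c(0, 0)` expresses the
  zero-anchor reading. The default follows the IOM allowance. An equivalent
  reparameterisation via published per-trimester weekly *rates* can be
  expressed by choosing anchors that reproduce those rates.
* **Fractional weeks.** The reference table is tabulated at integer weeks,
  but `weekly_range()` accepts fractional weeks, because cohort visits occur
  *approximately* at the nominal schedule and screening at the actual
  gestational age is more faithful than snapping to the label.

## The screening and outcome rules

At a visit in week $w$ with margin $m \in \{2, 5\}$ kg the test is positive
iff

$$\mathrm{gain} < \min(w) - m \quad\text{or}\quad \mathrm{gain} > \max(w) + m.$$

The inequalities are strict — a gain of exactly $\max(w) + m$ is still
"within" — because the rule's clinical wording is "greater than 2 kg or 5 kg
below/above". Gain is measured from the *reported* pre-pregnancy weight and
may be negative. The ±5 kg band strictly contains the ±2 kg band, so a ±5
positive is always a ±2 positive (tested as an invariant).

The reference standard ("total GWG outside recommendations") is the same
screen applied at the 36-week visit, with the outcome margin always equal to
the test margin: a ±2 kg test is judged against the ±2 kg outcome, ±5
against ±5. A consecutive-visit rule is the AND of two successive visits:
referral only when both are positive. On any cohort this composition can
only lose sensitivity and gain specificity relative to its component visits
— also property-tested.

Visit handling follows a complete-case logic mirroring the cohort-inclusion
rule of the motivating study (a reported pre-pregnancy weight, a 36-week
weight, and at least one earlier visit): a participant missing the final
visit is excluded from evaluation entirely; one missing only an interior
visit drops out of that visit's (and that pair's) analyses but is retained
elsewhere. Measurements are matched to nominal visits (19/24/30/36 weeks) by
nearest gestational age within ±3 weeks, a tolerance wide enough for
real-world scheduling but narrow enough that neighbouring nominal visits
cannot collide.

## Performance estimation

From the 2×2 table of test against outcome over eligible participants:
sensitivity $Se = tp/(tp+fn)$, specificity $Sp = tn/(fp+tn)$,
$LR^+ = Se/(1-Sp)$, $LR^- = (1-Se)/Sp$ — the identities hold to machine
precision for every emitted estimate.

The confidence-interval parameterisation was an open choice; the published
LR intervals this package's defaults were chosen to resemble are symmetric
about the point estimate, which identifies a natural-scale construction. The
default is therefore Wald intervals on the proportion scale for $Se$ and
$Sp$ and symmetric delta-method intervals on the natural scale for the LRs:

$$\operatorname{Var}(LR^+) \approx \frac{v_1}{(1-Sp)^2}
  + \frac{Se^2\,v_0}{(1-Sp)^4},$$

with $v_1 = Se(1-Se)/(tp+fn)$ and $v_0 = Sp(1-Sp)/(fp+tn)$ (analogously for
$LR^-$). `ci_method = "log"` switches to Clopper–Pearson proportions and the
standard log-scale LR interval. Proportion intervals are clipped to
$[0, 1]$ and LR intervals below at 0. Degenerate cells are reported as they
are — $Sp = 1$ gives $LR^+ = \infty$ with a flagged interval, $Se = 1$ gives
$LR^- = 0$ exactly — rather than silently continuity-corrected; a 0.5
correction exists but is off by default. Report files round estimates to
2 decimals and zone percentages to whole numbers, matching the precision
conventions of clinical screening tables.

## The synthetic cohort generator

No individual-level data from the motivating WATCH cohort are available, so
the package ships a generator whose *structure* emulates it: n = 131 with
category mix 7/68/29/27 (exact quotas on request), visits at nominal
19/24/30/36 weeks with Normal(0, 0.5 wk) gestational-age jitter clipped to
[13, 40], and 0.3 kg scale noise per measurement — a realistic repeatability
figure for calibrated clinic scales with clothed weighing.

The latent trajectory is the simplest model under which visit-level and
36-week zones have a controllable joint distribution: cumulative gain
$a + r\,(w-13)$ with per-category bivariate-normal $(a, r)$. The motivating
study fits no trajectories, so the form is the package's own. Per-category
means and SDs were calibrated once, by least squares on analytic
normal-zone probabilities, to the observed zone proportions at all four
visits and both margins, then frozen in `inst/extdata/sim_defaults.yaml`
(worst residual 14 percentage points, overweight category). Midpoint-centred
means cannot reproduce those proportions — the observed cohort is strongly
asymmetric (6 of 7 underweight women above range at every visit; obese women
drifting from below- toward above-range) — so the calibrated means sit off
the band midpoints by construction. A test guards the frozen defaults:
large-sample zone proportions must stay within ±15 percentage points of the
observed ones.

Self-reported pre-pregnancy weight can carry error: when enabled, a uniform
draw on [−2.94, 0.29] kg (the reported range for self-report minus measured
weight, i.e. mostly underestimation) is added to the reported baseline,
shifting every computed gain by exactly the negated error. It is off by
default because the primary analysis takes self-report at face value. The
error draw happens regardless so toggling the option perturbs nothing else
under a fixed seed.

`oracle_performance()` estimates a rule's *true* sensitivity and specificity
under the generative model by direct vectorised Monte Carlo over the latent
variables and noise, sharing only the weekly-range formula with the
screening pipeline. It assumes complete visits.

**What passing tests show — and do not.** The generator reproduces the
observed marginal zone distribution, the visit structure, and plausible
measurement error; it does not model curvature in gain trajectories
(e.g. third-trimester slowing), gestational diabetes or other covariates,
informative missingness, or the joint visit-to-visit transition dynamics of
the real cohort beyond what a linear random-intercept/slope model implies.
Agreement between pipeline estimates and the oracle therefore validates the
*software* end to end and the estimators' calibration under a known model —
it is not a claim that the simulated operating characteristics equal the
real cohort's published ones (the simulated specificity, for instance, runs
higher).

## Numerical and scale choices

Tests and checks use fixed seeds throughout; cohort simulation is
deterministic given a configuration and seed, byte for byte. Monte Carlo
sizes were chosen for stable comparisons at interactive runtimes: the oracle
uses $10^6$ draws where it serves as ground truth (zone probabilities stable
to ~3 decimals), pipeline-vs-oracle agreement is checked at $n = 10^5$
within 3 combined standard errors, property suites run on 200 randomised
cohorts of n = 60, and Wald-interval coverage is estimated over 500
replicates of n = 131 (accepted range 90–99%, since Wald intervals at this
n are approximate). Percentage-sum checks on rounded tables allow a 1.5-point
slack, the worst case for three independently rounded percentages.

## Known limitations

* The weekly range is linear between its anchors; guideline rate tables with
  trimester-specific slopes can be approximated but not matched exactly.
* Published confidence intervals from the motivating analysis are only
  approximately reproducible even from identical counts, because the exact
  mixed-model parameterisation used there is not recoverable.
* The 36-week screen is a proxy reference standard for total-pregnancy GWG;
  gain between 36 weeks and birth is ignored by construction.
* Underweight-category inputs rest on very few observed women (n = 7); both
  the calibration targets and any conclusions for that category are
  correspondingly fragile.
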