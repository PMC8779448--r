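# Latent gain-trajectory defaults for the synthetic WATCH-like cohort.
# Per BMI category: cumulative gain from week 13 is a + r * (week - 13) with
# (a, r) bivariate normal, correlation rho. Values were calibrated once by
# least squares against the observed WATCH zone proportions (visits
# 19/24/30/36, margins 2 and 5 kg) and are frozen; see the methods vignette.
# Units: a in kg (gain reached by week 13), r in kg/week.
underweight:
  mu_a: 6.7223
  mu_r: 0.57772
  sd_a: 2.0718
  sd_r: 0.11778
  rho: 0.0
normal:
  mu_a: 2.1702
  mu_r: 0.53060
  sd_a: 4.1848
  sd_r: 0.09907
  rho: 0.0
overweight:
  mu_a: 4.7028
  mu_r: 0.33653
  sd_a: 1.2485
  sd_r: 0.25125
  rho: 0.0
obese:
  mu_a: -0.9069
  mu_r: 0.39626
  sd_a: 5.6422
  sd_r: 0.22003
  rho: 0.0
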