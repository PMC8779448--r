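test_that("a fixed seed reproduces the cohort bit for bit", {
  cfg <- sim_config(n_participants = 50, seed = 123)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  # and a different seed does not
  s3 <- simulate_cohort(sim_config(n_participants = 50, seed = 124))
  expect_false(identical(s1$cohort$weight_kg, s3$cohort$weight_kg))
})

test_that("exact-quota mode reproduces the 7/68/29/27 category mix", {
  sim <- simulate_cohort(sim_config(
    n_participants = 131,
    quota_exact = TRUE, seed = 5
  ))
  counts <- table(sim$truth$bmi_category)
  expect_equal(
    unname(c(counts[c("underweight", "normal", "overweight", "obese")])),
    c(7L, 68L, 29L, 27L)
  )
  # drawn category always matches the anthropometry-derived one
  one <- dplyr::distinct(sim$cohort, participant_id, .keep_all = TRUE)
  derived <- bmi_category(one$prepregnancy_weight_kg, one$height_m)
  expect_equal(as.character(derived), one$bmi_category)
})

test_that("missingness spares the outcome visit; zero missingness is complete", {
  full <- simulate_cohort(sim_config(n_participants = 40, seed = 9))
  expect_equal(unname(c(table(full$cohort$participant_id))), rep(4L, 40))
  holey <- simulate_cohort(sim_config(
    n_participants = 200,
    visit_missingness_prob = 0.4, seed = 9
  ))
  per <- dplyr::summarise(
    dplyr::group_by(holey$cohort, participant_id),
    has_final = any(week > 33), .groups = "drop"
  )
  expect_true(all(per$has_final))
  expect_true(nrow(holey$cohort) < 200 * 4)
})

test_that("degenerate trajectories pin every screen to the expected zone", {
  # mid-band line: a at the allowance midpoint, rate to the total midpoint
  tg <- iom_targets()
  mid <- fixed_trajectory(
    a = 1.25,
    r = ((tg$total_min_kg + tg$total_max_kg) / 2 - 1.25) / 27
  )
  quiet <- sim_config(
    n_participants = 40, trajectory = mid,
    ga_jitter_sd = 0, measurement_noise_sd = 0, seed = 11
  )
  s <- screen_cohort(simulate_cohort(quiet)$cohort)
  expect_true(all(s$zone == "within"))
  expect_true(all(s$test_positive == 0L))

  # rate far above every category's maximum: positive everywhere
  runaway <- sim_config(
    n_participants = 40,
    trajectory = fixed_trajectory(a = 3, r = 1.5),
    ga_jitter_sd = 0, measurement_noise_sd = 0, seed = 12
  )
  sim <- simulate_cohort(runaway)
  s <- screen_cohort(sim$cohort)
  expect_true(all(s$zone == "above"))
  expect_true(all(sim$truth$true_outcome_2kg == 1L))
  expect_true(all(sim$truth$true_outcome_5kg == 1L))
})

test_that("self-report error shifts every computed GWG by exactly its negation", {
  base <- sim_config(n_participants = 60, seed = 33)
  with_err <- sim_config(
    n_participants = 60, seed = 33,
    selfreport_error = c(-2.94, 0.29)
  )
  off <- simulate_cohort(base)
  on <- simulate_cohort(with_err)
  g_off <- compute_gwg(off$cohort)$gwg_kg
  g_on <- compute_gwg(on$cohort)$gwg_kg
  err <- on$truth$selfreport_error_kg[
    match(on$cohort$participant_id, on$truth$participant_id)
  ]
  expect_equal(g_on, g_off - err, tolerance = 1e-12)
  expect_true(all(err >= -2.94 & err <= 0.29))
  # everything else is untouched
  expect_equal(off$cohort$weight_kg, on$cohort$weight_kg)
})

test_that("default trajectories stay near the observed zone proportions", {
  # regression guard on the frozen defaults: per-category zone proportions at
  # each visit and margin within 15 percentage points of the observed WATCH
  # distribution (large n, fixed seed)
  sim <- simulate_cohort(sim_config(n_participants = 60000, seed = 2718))
  screens <- screen_cohort(sim$cohort)
  got <- distribution_table(screens) # zone combinations kept complete
  got <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(got, margin_kg, visit, bmi_category),
    prop = count / sum(count)
  ))
  ref <- watch_distribution()
  ref <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(ref, margin_kg, visit, bmi_category),
    prop_ref = count / sum(count)
  ))
  m <- dplyr::inner_join(
    got[c("margin_kg", "visit", "bmi_category", "zone", "prop")],
    ref[c("margin_kg", "visit", "bmi_category", "zone", "prop_ref")],
    by = c("margin_kg", "visit", "bmi_category", "zone")
  )
  expect_equal(nrow(m), 96)
  expect_true(all(abs(m$prop - m$prop_ref) <= 0.15))
})

test_that("the Monte Carlo oracle is exact in degenerate and independent limits", {
  runaway <- sim_config(
    n_participants = 10,
    trajectory = fixed_trajectory(a = 3, r = 1.5),
    ga_jitter_sd = 0, measurement_noise_sd = 0
  )
  set.seed(61)
  o <- oracle_performance(runaway, "24", 2, n = 5000)
  expect_equal(o$sensitivity, 1)
  expect_equal(o$p_outcome_positive, 1)
  # huge pure noise at one visit, none at outcome: test independent of outcome,
  # so sensitivity ~= P(test positive)
  noisy <- sim_config(
    n_participants = 10,
    trajectory = fixed_trajectory(a = 1.25, r = 0.35),
    ga_jitter_sd = 0, measurement_noise_sd = 50
  )
  set.seed(62)
  o2 <- oracle_performance(noisy, "24", 2, n = 2e5)
  expect_equal(o2$sensitivity, o2$p_test_positive, tolerance = 0.02)
})
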