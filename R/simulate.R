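# Synthetic longitudinal cohorts with known latent gain trajectories,
# emulating the WATCH visit structure, plus an independent Monte Carlo
# oracle for the referral rules' true operating characteristics.

#' Trajectory parameter defaults
#'
#' Per-category parameters of the latent linear gain model: cumulative gain
#' from week 13 is `a + r * (week - 13)` with `(a, r)` bivariate normal.
#' Defaults were calibrated once against the observed WATCH zone proportions
#' and are stored in a versioned YAML file shipped with the package.
#'
#' @param path Optional alternative YAML file with the same layout.
#' @return Tibble `bmi_category, mu_a, mu_r, sd_a, sd_r, rho`.
#' @export
sim_trajectory_defaults <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sim_defaults.yaml",
      package = "gwgscreen", mustWork = TRUE
    )
  }
  raw <- yaml::read_yaml(path)
  if (!setequal(names(raw), bmi_levels())) {
    stop("trajectory file must define all four BMI categories", call. = FALSE)
  }
  dplyr::bind_rows(lapply(bmi_levels(), function(cc) {
    p <- raw[[cc]]
    tibble::tibble(
      bmi_category = cc, mu_a = p$mu_a, mu_r = p$mu_r,
      sd_a = p$sd_a, sd_r = p$sd_r, rho = p$rho %||% 0
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation configuration
#'
#' Bundles and validates every knob of the cohort generator. Defaults
#' reproduce the WATCH study conditions: n = 131 with BMI-category mix
#' 7/68/29/27, visits at nominal 19/24/30/36 weeks with 0.5-week gestational
#' age jitter, 0.3 kg scale noise, no missing visits, and pre-pregnancy
#' weight taken at face value (self-report error off; when enabled it is
#' uniform on [-2.94, 0.29] kg, the range reported for self-report vs
#' measured weight).
#'
#' @param n_participants Cohort size.
#' @param category_probs Probabilities over
#'   underweight/normal/overweight/obese (sum to 1).
#' @param visit_weeks Nominal visit schedule.
#' @param ga_jitter_sd SD (weeks) of actual-vs-nominal gestational age.
#' @param trajectory Tibble from [sim_trajectory_defaults()].
#' @param measurement_noise_sd SD (kg) of scale noise per measurement.
#' @param selfreport_error `NULL` (off) or length-2 interval (kg) of the
#'   uniform error added to the reported pre-pregnancy weight.
#' @param visit_missingness_prob Per-visit probability a measurement is
#'   missing (the final visit is never dropped so the outcome exists).
#' @param quota_exact Use exact per-category quotas (largest-remainder
#'   rounding of `n * category_probs`) instead of multinomial draws.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `gwg_sim_config`.
#' @export
sim_config <- function(n_participants = 131,
                       category_probs = c(7, 68, 29, 27) / 131,
                       visit_weeks = c(19, 24, 30, 36),
                       ga_jitter_sd = 0.5,
                       trajectory = sim_trajectory_defaults(),
                       measurement_noise_sd = 0.3,
                       selfreport_error = NULL,
                       visit_missingness_prob = 0,
                       quota_exact = FALSE,
                       seed = NULL) {
  stopifnot(
    n_participants >= 1,
    length(category_probs) == 4,
    all(category_probs >= 0),
    abs(sum(category_probs) - 1) < 1e-9,
    ga_jitter_sd >= 0, measurement_noise_sd >= 0,
    visit_missingness_prob >= 0, visit_missingness_prob < 1,
    all(visit_weeks >= 13 & visit_weeks <= 40)
  )
  stopifnot(all(c("mu_a", "mu_r", "sd_a", "sd_r", "rho") %in% names(trajectory)))
  stopifnot(all(trajectory$sd_a >= 0), all(trajectory$sd_r >= 0))
  if (!is.null(selfreport_error)) {
    stopifnot(length(selfreport_error) == 2, diff(selfreport_error) >= 0)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      category_probs = category_probs,
      visit_weeks = sort(visit_weeks),
      ga_jitter_sd = ga_jitter_sd,
      trajectory = trajectory,
      measurement_noise_sd = measurement_noise_sd,
      selfreport_error = selfreport_error,
      visit_missingness_prob = visit_missingness_prob,
      quota_exact = isTRUE(quota_exact),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "gwg_sim_config"
  )
}

# BMI ranges used to draw a pre-pregnancy weight inside the drawn category
category_bmi_ranges <- function() {
  tibble::tibble(
    bmi_category = bmi_levels(),
    bmi_lo = c(16.0, 18.5, 25.0, 30.0),
    bmi_hi = c(18.4, 24.9, 29.9, 42.0)
  )
}

draw_categories <- function(config) {
  n <- config$n_participants
  if (config$quota_exact) {
    raw <- n * config$category_probs
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      counts[order(raw - counts, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(raw - counts, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    sample(rep(bmi_levels(), times = counts))
  } else {
    sample(bmi_levels(), n, replace = TRUE, prob = config$category_probs)
  }
}

#' Simulate a WATCH-like longitudinal cohort
#'
#' Draws, per woman: a BMI category, a height and a pre-pregnancy weight
#' landing inside that category, a latent linear gain trajectory
#' `a + r * (week - 13)`, jittered gestational ages around the nominal
#' schedule (clipped to `[13, 40]`), and noisy scale weights. The observed
#' cohort table follows the long-format schema consumed by
#' [screen_cohort()]; the latent truth (trajectory and the noise-free
#' 36-week outcome at both margins) is returned alongside. Identical
#' configuration and seed give identical output; toggling the self-report
#' error changes only the reported pre-pregnancy weight.
#'
#' @param config From [sim_config()].
#' @return List with `cohort` (long tibble: `participant_id,
#'   prepregnancy_weight_kg, height_m, week, weight_kg, bmi_category`) and
#'   `truth` (`participant_id, bmi_category, a_i, r_i, selfreport_error_kg,
#'   true_outcome_2kg, true_outcome_5kg`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "gwg_sim_config"))
  if (!is.null(config$seed)) {
    set.seed(config$seed)
  }
  n <- config$n_participants
  nv <- length(config$visit_weeks)
  id <- sprintf("P%05d", seq_len(n))

  # fixed draw order keeps streams aligned across config toggles
  cat <- draw_categories(config)
  height <- pmin(pmax(stats::rnorm(n, 1.63, 0.065), 1.45), 1.90)
  rng <- category_bmi_ranges()
  i <- match(cat, rng$bmi_category)
  bmi <- stats::runif(n, rng$bmi_lo[i], rng$bmi_hi[i])
  prepreg_true <- bmi * height^2
  tr <- config$trajectory[match(cat, tr_cat(config$trajectory)), ]
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  a <- tr$mu_a + tr$sd_a * z1
  r <- tr$mu_r + tr$sd_r * (tr$rho * z1 + sqrt(1 - tr$rho^2) * z2)
  err <- stats::runif(n, -2.94, 0.29) # drawn always, applied when enabled
  jitter <- matrix(stats::rnorm(n * nv, 0, config$ga_jitter_sd), n, nv)
  noise <- matrix(stats::rnorm(n * nv, 0, config$measurement_noise_sd), n, nv)
  miss <- matrix(stats::runif(n * nv) < config$visit_missingness_prob, n, nv)
  miss[, nv] <- FALSE # outcome visit always observed

  apply_err <- !is.null(config$selfreport_error)
  if (apply_err) {
    # rescale the pre-drawn uniform onto the requested interval
    lo <- config$selfreport_error[1]
    hi <- config$selfreport_error[2]
    err <- lo + (err + 2.94) / (0.29 + 2.94) * (hi - lo)
  }
  prepreg_reported <- prepreg_true + if (apply_err) err else 0

  weeks <- pmin(pmax(
    matrix(config$visit_weeks, n, nv, byrow = TRUE) + jitter, 13
  ), 40)
  gain <- a + r * (weeks - 13)
  weight <- prepreg_true + gain + noise

  keep <- !as.vector(miss)
  cohort <- tibble::tibble(
    participant_id = rep(id, nv),
    prepregnancy_weight_kg = rep(prepreg_reported, nv),
    height_m = rep(height, nv),
    week = as.vector(weeks),
    weight_kg = as.vector(weight),
    bmi_category = rep(cat, nv)
  )[keep, , drop = FALSE]
  cohort <- dplyr::arrange(cohort, .data$participant_id, .data$week)

  out36 <- function(margin) {
    s <- screen_visit(a + r * 23, 36, cat, margin)
    s$test_positive
  }
  truth <- tibble::tibble(
    participant_id = id,
    bmi_category = cat,
    a_i = a,
    r_i = r,
    selfreport_error_kg = if (apply_err) err else 0,
    true_outcome_2kg = out36(2),
    true_outcome_5kg = out36(5)
  )
  list(cohort = cohort, truth = truth)
}

tr_cat <- function(trajectory) as.character(trajectory$bmi_category)

#' True operating characteristics of a referral rule under the simulator
#'
#' Independent brute-force Monte Carlo estimate of a rule's sensitivity and
#' specificity under the generative model: latent trajectories, gestational
#' age jitter, scale noise and (if enabled) self-report error are drawn
#' directly and the rule and 36-week reference standard are scored from the
#' weekly range formula, without going through the cohort-table screening
#' pipeline. Visits are assumed complete.
#'
#' @param config From [sim_config()].
#' @param rule Rule label (`"24"` or `"19+24"` style).
#' @param margin_kg Referral margin, 2 or 5.
#' @param n Number of Monte Carlo draws (default 1e6).
#' @param outcome_visit Nominal outcome visit (default 36).
#' @param targets Targets table from [iom_targets()].
#' @return List `sensitivity, specificity, p_test_positive,
#'   p_outcome_positive, n`.
#' @export
oracle_performance <- function(config, rule, margin_kg, n = 1e6,
                               outcome_visit = 36, targets = iom_targets()) {
  stopifnot(inherits(config, "gwg_sim_config"))
  visits <- parse_rule(rule)
  cat <- sample(bmi_levels(), n,
    replace = TRUE, prob = config$category_probs
  )
  tr <- config$trajectory[match(cat, tr_cat(config$trajectory)), ]
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  a <- tr$mu_a + tr$sd_a * z1
  r <- tr$mu_r + tr$sd_r * (tr$rho * z1 + sqrt(1 - tr$rho^2) * z2)
  e <- if (!is.null(config$selfreport_error)) {
    stats::runif(n, config$selfreport_error[1], config$selfreport_error[2])
  } else {
    0
  }
  ti <- match(cat, as.character(targets$bmi_category))
  flag_at <- function(nominal_week) {
    w <- pmin(pmax(
      nominal_week + stats::rnorm(n, 0, config$ga_jitter_sd), 13
    ), 40)
    gwg <- a + r * (w - 13) + stats::rnorm(n, 0, config$measurement_noise_sd) - e
    b <- range_at_week(
      w, targets$total_min_kg[ti], targets$total_max_kg[ti],
      targets$ft_min_kg[ti], targets$ft_max_kg[ti]
    )
    gwg < b$min_kg - margin_kg | gwg > b$max_kg + margin_kg
  }
  test <- flag_at(visits[1])
  for (v in visits[-1]) test <- test & flag_at(v)
  outcome <- flag_at(outcome_visit)
  list(
    sensitivity = mean(test[outcome]),
    specificity = mean(!test[!outcome]),
    p_test_positive = mean(test),
    p_outcome_positive = mean(outcome),
    n = n
  )
}
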