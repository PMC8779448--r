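# Builders for tiny in-code cohorts and randomised simulator configs.

# One participant's long-format rows from a visit table.
participant_rows <- function(id, prepreg, height, visits,
                             category = NULL) {
  out <- tibble::tibble(
    participant_id = id,
    prepregnancy_weight_kg = prepreg,
    height_m = height,
    week = visits$week,
    weight_kg = visits$weight_kg
  )
  if (!is.null(category)) out$bmi_category <- category
  out
}

# A normal-category woman (BMI 24.8) with on-schedule visits and given gains.
gain_cohort <- function(gains_by_id, prepreg = 70, height = 1.68,
                        weeks = c(19, 24, 30, 36)) {
  dplyr::bind_rows(lapply(names(gains_by_id), function(id) {
    g <- gains_by_id[[id]]
    participant_rows(
      id, prepreg, height,
      tibble::tibble(week = weeks[seq_along(g)], weight_kg = prepreg + g)
    )
  }))
}

# Random but valid simulator config for property tests.
random_config <- function(n = 60) {
  p <- stats::runif(4)
  tr <- sim_trajectory_defaults()
  tr$mu_a <- tr$mu_a + stats::rnorm(4, 0, 1)
  tr$mu_r <- pmax(tr$mu_r + stats::rnorm(4, 0, 0.1), 0.01)
  tr$sd_a <- tr$sd_a * stats::runif(4, 0.5, 1.5)
  tr$sd_r <- tr$sd_r * stats::runif(4, 0.5, 1.5)
  sim_config(
    n_participants = n,
    category_probs = p / sum(p),
    trajectory = tr,
    seed = sample.int(1e6, 1)
  )
}

# Degenerate trajectory: every woman follows the exact same line.
fixed_trajectory <- function(a, r) {
  tibble::tibble(
    bmi_category = bmi_levels(),
    mu_a = a, mu_r = r, sd_a = 0, sd_r = 0, rho = 0
  )
}
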