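# Per-visit GWG screening: +/-2 kg and +/-5 kg referral tests against the
# weekly expected range, at single visits and consecutive visit pairs.

#' Attach nominal visit labels to a longitudinal cohort
#'
#' Each measurement row is assigned to the nearest nominal visit week within
#' `tolerance` weeks; rows with no nominal visit in reach are dropped, and
#' when several rows of one participant compete for the same nominal visit
#' the closest (earliest on ties) wins. Screening later scores gain against
#' the range at the *actual* gestational age, not the nominal label, unless
#' asked otherwise.
#'
#' @param cohort Long-format tibble with at least `participant_id`, `week`.
#' @param visit_weeks Nominal visit schedule (default 19, 24, 30, 36 weeks).
#' @param tolerance Maximum |actual - nominal| in weeks (default 3).
#' @return `cohort` with an integer `visit` column, one row per
#'   participant-visit.
#' @export
assign_visits <- function(cohort, visit_weeks = c(19, 24, 30, 36),
                          tolerance = 3) {
  stopifnot(is.numeric(visit_weeks), length(visit_weeks) >= 1, tolerance > 0)
  d <- abs(outer(cohort$week, visit_weeks, "-"))
  j <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(cohort)), j)]
  out <- cohort
  out$visit <- visit_weeks[j]
  out$.dist <- dist
  out <- out[out$.dist <= tolerance, , drop = FALSE]
  out <- dplyr::arrange(out, .data$participant_id, .data$visit, .data$.dist, .data$week)
  out <- dplyr::distinct(out, .data$participant_id, .data$visit, .keep_all = TRUE)
  out$.dist <- NULL
  dplyr::arrange(out, .data$participant_id, .data$week)
}

#' Per-participant BMI category for a cohort
#'
#' An explicit `bmi_category` column overrides the value derived from
#' pre-pregnancy weight and height (supports datasets carrying only the
#' categorical BMI).
#'
#' @param cohort Long-format cohort tibble.
#' @return Tibble `participant_id`, `bmi_category` (one row per participant).
#' @export
cohort_categories <- function(cohort) {
  one <- dplyr::distinct(
    cohort, .data$participant_id,
    .keep_all = TRUE
  )
  if ("bmi_category" %in% names(cohort) && !all(is.na(one$bmi_category))) {
    cat <- factor(as.character(one$bmi_category), levels = bmi_levels())
    if (anyNA(cat)) {
      miss <- is.na(cat)
      cat[miss] <- bmi_category(
        one$prepregnancy_weight_kg[miss],
        one$height_m[miss]
      )
    }
  } else {
    cat <- bmi_category(one$prepregnancy_weight_kg, one$height_m)
  }
  tibble::tibble(participant_id = one$participant_id, bmi_category = cat)
}

#' Gestational weight gain from the pre-pregnancy baseline
#'
#' Gain is visit weight minus (self-reported) pre-pregnancy weight and may be
#' negative. With `week = NULL` every measurement row gets a `gwg_kg` column;
#' with a nominal `week`, one value per participant is returned and
#' participants without a matching visit get `NA` (they drop out of that
#' visit's analyses, nothing aborts).
#'
#' @param cohort Long-format cohort tibble.
#' @param week Optional nominal visit week to extract.
#' @param tolerance Visit-matching tolerance in weeks (see [assign_visits()]).
#' @return The cohort with a `gwg_kg` column, or a named numeric vector.
#' @export
compute_gwg <- function(cohort, week = NULL, tolerance = 3) {
  cohort$gwg_kg <- cohort$weight_kg - cohort$prepregnancy_weight_kg
  if (is.null(week)) {
    return(cohort)
  }
  v <- assign_visits(cohort, visit_weeks = week, tolerance = tolerance)
  ids <- unique(cohort$participant_id)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  out[as.character(v$participant_id)] <- v$gwg_kg
  out
}

#' Screen a gain value against the margin-adjusted expected range
#'
#' A test is positive when the cumulative gain falls strictly more than
#' `margin_kg` below the weekly minimum or strictly more than `margin_kg`
#' above the weekly maximum; equality with either adjusted bound still counts
#' as within (the referral wording is "greater than").
#'
#' @param gwg_kg Cumulative gain(s), kg.
#' @param week Gestational week(s) at measurement, in `[13, 40]`.
#' @param category BMI category (recycled).
#' @param margin_kg Referral margin, 2 or 5 kg.
#' @param targets Targets table from [iom_targets()].
#' @return Tibble `week, bmi_category, margin_kg, gwg_kg, zone,
#'   test_positive`; `zone` is a factor below/within/above.
#' @export
screen_visit <- function(gwg_kg, week, category, margin_kg,
                         targets = iom_targets()) {
  if (!all(margin_kg %in% c(2, 5))) {
    stop("`margin_kg` must be 2 or 5", call. = FALSE)
  }
  n <- max(
    length(gwg_kg), length(week), length(category), length(margin_kg)
  )
  rng <- weekly_range(rep_len(week, n), rep_len(category, n), targets)
  gwg_kg <- rep_len(gwg_kg, n)
  margin_kg <- rep_len(margin_kg, n)
  zone <- dplyr::case_when(
    gwg_kg < rng$min_kg - margin_kg ~ "below",
    gwg_kg > rng$max_kg + margin_kg ~ "above",
    .default = "within"
  )
  tibble::tibble(
    week = rng$week,
    bmi_category = rng$bmi_category,
    margin_kg = margin_kg,
    gwg_kg = gwg_kg,
    zone = factor(zone, levels = c("below", "within", "above")),
    test_positive = as.integer(zone != "within")
  )
}

#' Screen every matched visit of a cohort
#'
#' Computes per-visit GWG, matches measurements to the nominal visit
#' schedule, and applies the referral test at each requested margin.
#'
#' @inheritParams assign_visits
#' @inheritParams screen_visit
#' @param margins Margins to screen at (any subset of `c(2, 5)`).
#' @param use_actual_week Score against the range at the actual gestational
#'   age (default) or at the nominal visit week.
#' @return Tibble `participant_id, visit, week, bmi_category, margin_kg,
#'   gwg_kg, zone, test_positive`, one row per participant-visit-margin.
#' @export
screen_cohort <- function(cohort, margins = c(2, 5),
                          visit_weeks = c(19, 24, 30, 36), tolerance = 3,
                          use_actual_week = TRUE, targets = iom_targets()) {
  v <- assign_visits(compute_gwg(cohort), visit_weeks, tolerance)
  v <- dplyr::left_join(
    v[setdiff(names(v), "bmi_category")],
    cohort_categories(cohort),
    by = "participant_id"
  )
  score_week <- if (use_actual_week) v$week else v$visit
  res <- lapply(margins, function(m) {
    s <- screen_visit(v$gwg_kg, score_week, v$bmi_category, m, targets)
    tibble::tibble(
      participant_id = v$participant_id,
      visit = v$visit,
      week = v$week,
      bmi_category = s$bmi_category,
      margin_kg = m,
      gwg_kg = s$gwg_kg,
      zone = s$zone,
      test_positive = s$test_positive
    )
  })
  dplyr::arrange(
    dplyr::bind_rows(res),
    .data$participant_id, .data$visit, .data$margin_kg
  )
}

#' Participants eligible for rule evaluation
#'
#' Mirrors the cohort-inclusion rule: a participant enters the evaluation only
#' with a final (outcome) visit present and at least one earlier visit.
#'
#' @param screens Output of [screen_cohort()].
#' @param outcome_visit Nominal outcome visit (default 36 weeks).
#' @return Character vector of participant ids.
#' @export
eligible_ids <- function(screens, outcome_visit = 36) {
  per <- dplyr::summarise(
    dplyr::group_by(screens, .data$participant_id),
    has_final = any(.data$visit == outcome_visit),
    has_earlier = any(.data$visit < outcome_visit),
    .groups = "drop"
  )
  as.character(per$participant_id[per$has_final & per$has_earlier])
}

#' Reference-standard outcome at the final visit
#'
#' The 36-week screen result itself is the reference standard: outcome = 1
#' when total gain at the final visit lies outside the margin-adjusted range.
#' The outcome margin always equals the test margin.
#'
#' @inheritParams eligible_ids
#' @return Tibble `participant_id, margin_kg, outcome` for participants with
#'   the final visit; others are ineligible and absent.
#' @export
final_outcome <- function(screens, outcome_visit = 36) {
  fin <- screens[screens$visit == outcome_visit, , drop = FALSE]
  tibble::tibble(
    participant_id = fin$participant_id,
    margin_kg = fin$margin_kg,
    outcome = fin$test_positive
  )
}

#' Consecutive-visit referral rule (AND composition)
#'
#' Referral is triggered only when the test is positive at both of two
#' successive visits; every other combination scores 0.
#'
#' @param result_a,result_b Screen-result rows (equal-length data frames with
#'   `participant_id, visit, margin_kg, test_positive`) for the same
#'   participants and margin at two distinct visits.
#' @return Integer vector of referral indicators.
#' @export
consecutive_rule <- function(result_a, result_b) {
  if (nrow(result_a) != nrow(result_b)) {
    stop("screen results must pair one-to-one", call. = FALSE)
  }
  if (!all(result_a$participant_id == result_b$participant_id) ||
    !all(result_a$margin_kg == result_b$margin_kg)) {
    stop("consecutive rule requires matching participant and margin",
      call. = FALSE
    )
  }
  if (any(result_a$visit == result_b$visit)) {
    stop("consecutive rule requires two distinct visits", call. = FALSE)
  }
  as.integer(result_a$test_positive == 1L & result_b$test_positive == 1L)
}

#' Count screen-positive participants at a visit
#'
#' Works on raw screen results or on a distribution table (where the count of
#' positives is the sum of below + above counts over BMI categories).
#'
#' @param x Output of [screen_cohort()] or [distribution_table()] (any tibble
#'   with a `count` column is treated as a distribution table).
#' @param visit Nominal visit week.
#' @param margin_kg Referral margin, 2 or 5.
#' @return Integer count.
#' @export
count_positives <- function(x, visit, margin_kg) {
  sel <- x[x$visit == visit & x$margin_kg == margin_kg, , drop = FALSE]
  if (nrow(sel) == 0 && nrow(x) > 0) {
    stop("visit ", visit, " (margin ", margin_kg, ") absent", call. = FALSE)
  }
  if ("count" %in% names(x)) {
    return(sum(sel$count[sel$zone != "within"]))
  }
  sum(sel$test_positive)
}

#' Distribution of gain zones by visit, margin and BMI category
#'
#' Counts and within-category percentages (rounded to whole numbers) of
#' participants below, within, or above the margin-adjusted expected range at
#' each visit.
#'
#' @inheritParams eligible_ids
#' @return Tibble `margin_kg, visit, bmi_category, zone, count, pct`; the
#'   three zone counts of a visit-category cell sum to the number of that
#'   category's participants measured at that visit.
#' @export
distribution_table <- function(screens) {
  out <- dplyr::count(
    screens, .data$margin_kg, .data$visit, .data$bmi_category, .data$zone,
    name = "count", .drop = FALSE
  )
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$margin_kg, .data$visit, .data$bmi_category),
    pct = if (sum(.data$count) > 0) {
      round(100 * .data$count / sum(.data$count))
    } else {
      rep(NA_real_, dplyr::n())
    }
  )
  dplyr::ungroup(out)
}

#' Observed WATCH zone distribution
#'
#' The published per-visit, per-category counts of women below, within and
#' above the margin-adjusted expected range in the WATCH cohort (n = 131;
#' 7/68/29/27 across underweight/normal/overweight/obese). Used as an input
#' table for referral-burden arithmetic and as the calibration target of the
#' cohort simulator.
#'
#' @return Tibble `margin_kg, visit, bmi_category, zone, count`.
#' @export
watch_distribution <- function() {
  path <- system.file("extdata", "watch_table1_counts.csv",
    package = "gwgscreen", mustWork = TRUE
  )
  out <- readr::read_csv(path, col_types = readr::cols(
    margin_kg = readr::col_double(),
    visit = readr::col_double(),
    bmi_category = readr::col_character(),
    zone = readr::col_character(),
    count = readr::col_double()
  ))
  out$bmi_category <- factor(out$bmi_category, levels = bmi_levels())
  out$zone <- factor(out$zone, levels = c("below", "within", "above"))
  out
}
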