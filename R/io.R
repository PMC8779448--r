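# Cohort file ingestion/validation and report rendering.

cohort_required_cols <- c(
  "participant_id", "prepregnancy_weight_kg", "height_m", "week", "weight_kg"
)

#' Read and validate a long-format cohort CSV
#'
#' Expected header: `participant_id,prepregnancy_weight_kg,height_m,week,`
#' `weight_kg[,bmi_category]`; one row per visit, UTF-8, dot decimal, missing
#' values empty. A malformed header is a hard error. Rows with missing
#' anthropometry or a gestational week outside `[13, 40]` are rejected with
#' row-numbered warnings; duplicate participant-week rows resolve last-wins
#' with a warning. Validation counts (including eligibility under the
#' has-final-visit-plus-one-earlier inclusion rule) are attached as the
#' `"validation"` attribute and reported via `message()`.
#'
#' @param path CSV file path.
#' @param outcome_visit Nominal outcome visit for the eligibility count.
#' @param tolerance Visit-matching tolerance in weeks.
#' @param visit_weeks Nominal visit schedule.
#' @param quiet Suppress the summary message.
#' @return Cohort tibble sorted by participant and week, with attribute
#'   `"validation"`.
#' @export
read_cohort <- function(path, outcome_visit = 36, tolerance = 3,
                        visit_weeks = c(19, 24, 30, 36), quiet = FALSE) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols()))
  missing_cols <- setdiff(cohort_required_cols, header)
  if (length(missing_cols) > 0) {
    stop("cohort file ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  x <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    prepregnancy_weight_kg = readr::col_double(),
    height_m = readr::col_double(),
    week = readr::col_double(),
    weight_kg = readr::col_double(),
    .default = readr::col_character()
  ))
  n_raw <- nrow(x)

  bad <- !is.finite(x$prepregnancy_weight_kg) | x$prepregnancy_weight_kg <= 0 |
    !is.finite(x$height_m) | x$height_m <= 0 |
    !is.finite(x$weight_kg) |
    !is.finite(x$week) | x$week < 13 | x$week > 40
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed row(s): ",
      paste(utils::head(which(bad), 10), collapse = ", "),
      if (sum(bad) > 10) ", ..." else "",
      call. = FALSE
    )
    x <- x[!bad, , drop = FALSE]
  }

  dup <- duplicated(x[c("participant_id", "week")], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate participant-week row(s); keeping the last",
      call. = FALSE
    )
    x <- x[!dup, , drop = FALSE]
  }
  x <- dplyr::arrange(x, .data$participant_id, .data$week)

  ids <- unique(x$participant_id)
  v <- assign_visits(x, visit_weeks, tolerance)
  elig <- eligible_ids(
    tibble::tibble(participant_id = v$participant_id, visit = v$visit),
    outcome_visit
  )
  report <- list(
    n_rows_read = n_raw,
    n_rows_rejected = sum(bad) + sum(dup),
    n_participants = length(ids),
    n_eligible = length(elig),
    n_excluded = length(ids) - length(elig)
  )
  if (!quiet) {
    message(
      "cohort: ", report$n_participants, " participants (",
      report$n_eligible, " eligible, ", report$n_excluded,
      " excluded); ", report$n_rows_rejected, " row(s) rejected"
    )
  }
  attr(x, "validation") <- report
  x
}

#' Write a cohort (or any result tibble) as CSV
#'
#' @param x Tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(x)
}

round_cols <- function(x, cols, digits) {
  for (cc in intersect(cols, names(x))) x[[cc]] <- round(x[[cc]], digits)
  x
}

#' Render the standard report files
#'
#' Writes, under `dir`: `distribution.csv` (zone counts with whole-number
#' percentages), `performance_single.csv` and `performance_consecutive.csv`
#' (estimates to 2 decimals), `consecutive_referrals.csv` (frequencies with
#' percentages to 2 decimals) and a human-readable `summary.txt`. Empty
#' inputs yield header-only files.
#'
#' @param screens Output of [screen_cohort()].
#' @param dir Output directory (created if needed).
#' @param rules Rule grid for [evaluate_screens()] (default grid when
#'   `NULL`).
#' @param ci_method,conf_level Passed to [estimate_performance()].
#' @param outcome_visit Nominal outcome visit.
#' @return Invisible named list of the file paths written.
#' @export
render_reports <- function(screens, dir, rules = NULL,
                           ci_method = "wald-delta", conf_level = 0.95,
                           outcome_visit = 36) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    distribution = file.path(dir, "distribution.csv"),
    performance_single = file.path(dir, "performance_single.csv"),
    consecutive_referrals = file.path(dir, "consecutive_referrals.csv"),
    performance_consecutive = file.path(dir, "performance_consecutive.csv"),
    summary = file.path(dir, "summary.txt")
  )
  est_cols <- c(
    "sensitivity", "sens_lo", "sens_hi", "specificity", "spec_lo", "spec_hi",
    "lr_pos", "lrp_lo", "lrp_hi", "lr_neg", "lrn_lo", "lrn_hi"
  )
  empty_perf <- tibble::tibble(
    rule = character(), margin_kg = double(), tp = integer(), fp = integer(),
    fn = integer(), tn = integer(), n = integer()
  )
  if (nrow(screens) == 0) {
    readr::write_csv(tibble::tibble(
      margin_kg = double(), visit = double(), bmi_category = character(),
      zone = character(), count = integer(), pct = double()
    ), paths$distribution)
    readr::write_csv(empty_perf, paths$performance_single)
    readr::write_csv(tibble::tibble(
      pair = character(), first = character(), second = character(),
      referral = integer(), count = integer(), pct = double()
    ), paths$consecutive_referrals)
    readr::write_csv(empty_perf, paths$performance_consecutive)
    writeLines("empty cohort: no results", paths$summary)
    return(invisible(paths))
  }

  if (is.null(rules)) rules <- default_rule_grid()
  dist <- distribution_table(screens)
  readr::write_csv(dist, paths$distribution)

  perf <- evaluate_screens(screens, rules, outcome_visit,
    ci_method = ci_method, conf_level = conf_level
  )
  single <- round_cols(
    perf[!grepl("+", perf$rule, fixed = TRUE), , drop = FALSE], est_cols, 2
  )
  consec <- round_cols(
    perf[grepl("+", perf$rule, fixed = TRUE), , drop = FALSE], est_cols, 2
  )
  readr::write_csv(single, paths$performance_single)
  readr::write_csv(consec, paths$performance_consecutive)

  pairs <- unique(consec$rule)
  ref_tab <- if (length(pairs) > 0) {
    consecutive_referral_table(screens,
      pairs = pairs,
      margin_kg = min(consec$margin_kg), outcome_visit = outcome_visit
    )
  } else {
    tibble::tibble(
      pair = character(), first = character(), second = character(),
      referral = integer(), count = integer(), pct = double()
    )
  }
  readr::write_csv(ref_tab, paths$consecutive_referrals)

  n_part <- length(unique(screens$participant_id))
  n_elig <- length(eligible_ids(screens, outcome_visit))
  lines <- c(
    sprintf(
      "GWG screening summary: %d participants screened, %d eligible",
      n_part, n_elig
    ),
    "",
    "Screen-positive counts (referral burden):"
  )
  for (m in sort(unique(screens$margin_kg))) {
    for (v in sort(unique(screens$visit))) {
      lines <- c(lines, sprintf(
        "  visit %g wk, +/-%g kg: %d positive",
        v, m, count_positives(screens, v, m)
      ))
    }
  }
  if (nrow(perf) > 0) {
    lines <- c(lines, "", "Rule performance (sens / spec / LR+ / LR-):")
    for (i in seq_len(nrow(perf))) {
      lines <- c(lines, sprintf(
        "  %-6s +/-%g kg: %.2f / %.2f / %.2f / %.2f",
        perf$rule[i], perf$margin_kg[i], perf$sensitivity[i],
        perf$specificity[i], perf$lr_pos[i], perf$lr_neg[i]
      ))
    }
  }
  writeLines(lines, paths$summary)
  invisible(paths)
}
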