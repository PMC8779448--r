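# Diagnostic performance of the referral rules: 2x2 cross-tabulation against
# the 36-week outcome, sensitivity/specificity and likelihood ratios with
# 95% confidence intervals.

#' Cross-tabulate test against outcome
#'
#' Builds the 2x2 confusion table over the participants present in both flag
#' sets. Flags are tibbles with `participant_id` and a 0/1 column (`flag`).
#'
#' @param test_flags Tibble `participant_id, flag` for the screening test.
#' @param outcome_flags Tibble `participant_id, flag` for the 36-week
#'   reference standard.
#' @param label Optional description of the rule.
#' @return One-row tibble `label, tp, fp, fn, tn, n`.
#' @export
cross_tabulate <- function(test_flags, outcome_flags, label = NA_character_) {
  m <- dplyr::inner_join(test_flags, outcome_flags,
    by = "participant_id", suffix = c("_test", "_outcome")
  )
  if (nrow(m) == 0) {
    stop("no participants have both a test and an outcome", call. = FALSE)
  }
  t <- m$flag_test
  o <- m$flag_outcome
  tibble::tibble(
    label = label,
    tp = sum(t == 1 & o == 1),
    fp = sum(t == 1 & o == 0),
    fn = sum(t == 0 & o == 1),
    tn = sum(t == 0 & o == 0),
    n = nrow(m)
  )
}

# z quantile for a two-sided interval
z_for <- function(conf_level) stats::qnorm(1 - (1 - conf_level) / 2)

#' Sensitivity, specificity and likelihood ratios from a 2x2 table
#'
#' Point estimates obey the likelihood-ratio identities
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`. The default
#' intervals are Wald intervals on the proportion scale for sensitivity and
#' specificity, and symmetric delta-method intervals on the natural scale for
#' the likelihood ratios (the `"log"` alternative uses the standard
#' log-scale LR interval and Clopper-Pearson proportions). Proportion
#' intervals are clipped to `[0, 1]` and LR intervals below at 0. A
#' specificity of 1 makes LR+ infinite (flagged via `degenerate`); a
#' sensitivity of 1 makes LR- exactly 0.
#'
#' @param tab One-row confusion table from [cross_tabulate()] (or any list
#'   with `tp, fp, fn, tn`).
#' @param ci_method `"wald-delta"` (default) or `"log"`.
#' @param conf_level Confidence level (default 0.95).
#' @param continuity Add 0.5 to every cell before estimation (off by
#'   default).
#' @return One-row tibble with `sensitivity`, `specificity`, `lr_pos`,
#'   `lr_neg`, their `_lo`/`_hi` interval bounds, and a `degenerate` flag.
#' @examples
#' estimate_performance(list(tp = 40, fn = 10, fp = 14, tn = 36))
#' @export
estimate_performance <- function(tab, ci_method = c("wald-delta", "log"),
                                 conf_level = 0.95, continuity = FALSE) {
  ci_method <- match.arg(ci_method)
  tp <- tab$tp
  fp <- tab$fp
  fn <- tab$fn
  tn <- tab$tn
  if (continuity) {
    tp <- tp + 0.5
    fp <- fp + 0.5
    fn <- fn + 0.5
    tn <- tn + 0.5
  }
  n1 <- tp + fn
  n0 <- fp + tn
  if (n1 <= 0 || n0 <= 0) {
    stop("both outcome arms must be non-empty (tp+fn > 0 and fp+tn > 0)",
      call. = FALSE
    )
  }
  sens <- tp / n1
  spec <- tn / n0
  lr_pos <- if (spec < 1) sens / (1 - spec) else Inf
  lr_neg <- if (spec > 0) (1 - sens) / spec else Inf
  z <- z_for(conf_level)
  if (ci_method == "wald-delta") {
    v1 <- sens * (1 - sens) / n1
    v0 <- spec * (1 - spec) / n0
    sens_ci <- sens + c(-1, 1) * z * sqrt(v1)
    spec_ci <- spec + c(-1, 1) * z * sqrt(v0)
    # delta method on the natural LR scale: symmetric about the estimate
    if (is.finite(lr_pos)) {
      se_lrp <- sqrt(v1 / (1 - spec)^2 + v0 * sens^2 / (1 - spec)^4)
      lrp_ci <- lr_pos + c(-1, 1) * z * se_lrp
    } else {
      lrp_ci <- c(NA_real_, NA_real_)
    }
    if (is.finite(lr_neg) && spec > 0) {
      se_lrn <- sqrt(v1 / spec^2 + v0 * (1 - sens)^2 / spec^4)
      lrn_ci <- lr_neg + c(-1, 1) * z * se_lrn
    } else {
      lrn_ci <- c(NA_real_, NA_real_)
    }
  } else {
    sens_ci <- stats::binom.test(round(tp), round(n1),
      conf.level = conf_level
    )$conf.int
    spec_ci <- stats::binom.test(round(tn), round(n0),
      conf.level = conf_level
    )$conf.int
    # log-scale LR interval: se(log LR+) = sqrt((1-sens)/tp + spec/fp)
    if (is.finite(lr_pos) && tp > 0 && fp > 0) {
      se <- sqrt((1 - sens) / tp + spec / fp)
      lrp_ci <- exp(log(lr_pos) + c(-1, 1) * z * se)
    } else {
      lrp_ci <- c(NA_real_, NA_real_)
    }
    if (is.finite(lr_neg) && lr_neg > 0 && fn > 0 && tn > 0) {
      se <- sqrt(sens / fn + (1 - spec) / tn)
      lrn_ci <- exp(log(lr_neg) + c(-1, 1) * z * se)
    } else {
      lrn_ci <- c(NA_real_, NA_real_)
    }
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  tibble::tibble(
    sensitivity = sens,
    sens_lo = clip01(sens_ci[1]), sens_hi = clip01(sens_ci[2]),
    specificity = spec,
    spec_lo = clip01(spec_ci[1]), spec_hi = clip01(spec_ci[2]),
    lr_pos = lr_pos,
    lrp_lo = max(lrp_ci[1], 0), lrp_hi = lrp_ci[2],
    lr_neg = lr_neg,
    lrn_lo = max(lrn_ci[1], 0), lrn_hi = lrn_ci[2],
    degenerate = !is.finite(lr_pos) || !is.finite(lr_neg) || lr_neg == 0
  )
}

#' Parse a rule label into its component visits
#'
#' Rules are given as character labels: a single nominal visit (`"24"`) or a
#' consecutive pair joined by `+` (`"19+24"`), evaluated as an AND
#' composition.
#'
#' @param rule Character label.
#' @return Numeric vector of nominal visit weeks.
#' @export
parse_rule <- function(rule) {
  v <- suppressWarnings(as.numeric(strsplit(rule, "+", fixed = TRUE)[[1]]))
  if (anyNA(v) || length(v) < 1 || length(v) > 2) {
    stop("rule must be a visit week or a 'a+b' pair: ", rule, call. = FALSE)
  }
  v
}

# test flags (participant_id, flag) for one rule x margin on screen results
rule_flags <- function(screens, rule, margin_kg) {
  visits <- parse_rule(rule)
  s <- screens[screens$margin_kg == margin_kg &
    screens$visit %in% visits, , drop = FALSE]
  per <- dplyr::summarise(
    dplyr::group_by(s, .data$participant_id),
    n_visits = dplyr::n(),
    flag = as.integer(all(.data$test_positive == 1L)),
    .groups = "drop"
  )
  # AND rules need every component visit observed
  per <- per[per$n_visits == length(visits), c("participant_id", "flag")]
  per
}

#' Evaluate a grid of referral rules against the 36-week outcome
#'
#' For each rule (single visit or consecutive pair) and margin, screens are
#' cross-tabulated against the final-visit reference standard over eligible
#' participants with complete data for the rule, and performance is
#' estimated. The default grid covers single visits 19/24/30 at both margins
#' and the consecutive pairs 19+24 and 24+30 at +/-2 kg.
#'
#' @param cohort Long-format cohort tibble (see [read_cohort()]).
#' @param rules Tibble `rule, margin_kg`, or `NULL` for the default grid.
#' @param outcome_visit Nominal outcome visit (default 36).
#' @param ci_method,conf_level Passed to [estimate_performance()].
#' @inheritParams screen_cohort
#' @return Tibble with one row per rule: the confusion counts and the
#'   performance estimates.
#' @export
evaluate_rules <- function(cohort, rules = NULL, outcome_visit = 36,
                           ci_method = "wald-delta", conf_level = 0.95,
                           visit_weeks = c(19, 24, 30, 36), tolerance = 3,
                           use_actual_week = TRUE, targets = iom_targets()) {
  if (is.null(rules)) {
    rules <- default_rule_grid()
  }
  screens <- screen_cohort(cohort,
    margins = unique(rules$margin_kg),
    visit_weeks = visit_weeks, tolerance = tolerance,
    use_actual_week = use_actual_week, targets = targets
  )
  evaluate_screens(screens, rules, outcome_visit, ci_method, conf_level)
}

#' @rdname evaluate_rules
#' @param screens Pre-computed output of [screen_cohort()].
#' @export
evaluate_screens <- function(screens, rules = NULL, outcome_visit = 36,
                             ci_method = "wald-delta", conf_level = 0.95) {
  if (is.null(rules)) {
    rules <- default_rule_grid()
  }
  keep <- eligible_ids(screens, outcome_visit)
  screens <- screens[screens$participant_id %in% keep, , drop = FALSE]
  outcomes <- final_outcome(screens, outcome_visit)
  out <- vector("list", nrow(rules))
  for (i in seq_len(nrow(rules))) {
    rule <- rules$rule[i]
    m <- rules$margin_kg[i]
    tf <- rule_flags(screens, rule, m)
    of <- outcomes[outcomes$margin_kg == m, , drop = FALSE]
    of <- tibble::tibble(participant_id = of$participant_id, flag = of$outcome)
    common <- intersect(tf$participant_id, of$participant_id)
    if (length(common) == 0) {
      warning("rule ", rule, " (margin ", m, "): no eligible participants; ",
        "skipped",
        call. = FALSE
      )
      next
    }
    tab <- cross_tabulate(tf, of, label = rule)
    est <- estimate_performance(tab,
      ci_method = ci_method,
      conf_level = conf_level
    )
    out[[i]] <- dplyr::bind_cols(
      tibble::tibble(rule = rule, margin_kg = m), tab[-1], est
    )
  }
  dplyr::bind_rows(out)
}

#' Default referral-rule grid
#'
#' Single visits 19, 24, 30 at both margins; consecutive pairs 19+24 and
#' 24+30 at +/-2 kg only.
#'
#' @return Tibble `rule, margin_kg`.
#' @export
default_rule_grid <- function() {
  tibble::tibble(
    rule = c("19", "24", "30", "19", "24", "30", "19+24", "24+30"),
    margin_kg = c(2, 2, 2, 5, 5, 5, 2, 2)
  )
}

#' Consecutive-visit referral frequency table
#'
#' For each visit pair, cross-classifies participants by their referral
#' status at the two component visits and reports frequencies with
#' percentages of the eligible cohort (2 decimals); only the Refer/Refer row
#' carries referral indicator 1.
#'
#' @inheritParams evaluate_screens
#' @param pairs Character vector of pair rules (default `c("19+24",
#'   "24+30")`).
#' @param margin_kg Referral margin (default 2).
#' @return Tibble `pair, first, second, referral, count, pct` with four rows
#'   per pair.
#' @export
consecutive_referral_table <- function(screens, pairs = c("19+24", "24+30"),
                                       margin_kg = 2, outcome_visit = 36) {
  keep <- eligible_ids(screens, outcome_visit)
  screens <- screens[screens$participant_id %in% keep, , drop = FALSE]
  lvls <- c("No referral", "Refer")
  out <- lapply(pairs, function(p) {
    visits <- parse_rule(p)
    s <- screens[screens$margin_kg == margin_kg, , drop = FALSE]
    a <- s[s$visit == visits[1], c("participant_id", "test_positive")]
    b <- s[s$visit == visits[2], c("participant_id", "test_positive")]
    m <- dplyr::inner_join(a, b, by = "participant_id", suffix = c("_1", "_2"))
    grid <- tidyr::expand_grid(
      first = factor(lvls, levels = lvls),
      second = factor(lvls, levels = lvls)
    )
    cnt <- dplyr::count(
      tibble::tibble(
        first = factor(lvls[m$test_positive_1 + 1], levels = lvls),
        second = factor(lvls[m$test_positive_2 + 1], levels = lvls)
      ),
      .data$first, .data$second,
      name = "count", .drop = FALSE
    )
    cnt <- dplyr::left_join(grid, cnt, by = c("first", "second"))
    cnt$count[is.na(cnt$count)] <- 0L
    tibble::tibble(
      pair = p,
      first = cnt$first,
      second = cnt$second,
      referral = as.integer(cnt$first == "Refer" & cnt$second == "Refer"),
      count = cnt$count,
      pct = round(100 * cnt$count / sum(cnt$count), 2)
    )
  })
  dplyr::bind_rows(out)
}
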