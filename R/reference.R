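# Weekly expected gestational weight gain (GWG) ranges derived from the
# Institute of Medicine (IOM, 2009) total-pregnancy recommendations.

#' BMI category levels
#'
#' The four WHO pre-pregnancy BMI categories used throughout the package, in
#' increasing BMI order.
#'
#' @return Character vector `c("underweight", "normal", "overweight", "obese")`.
#' @export
bmi_levels <- function() {
  c("underweight", "normal", "overweight", "obese")
}

#' Classify pre-pregnancy BMI
#'
#' Computes BMI as `weight_kg / height_m^2` and assigns the WHO category.
#' Boundaries are half-open with the boundary value belonging to the heavier
#' category: BMI < 18.5 underweight, 18.5 to < 25 normal, 25 to < 30
#' overweight, and BMI >= 30 obese (grade is not subdivided).
#'
#' @param weight_kg Pre-pregnancy weight in kilograms (vectorised).
#' @param height_m Height in metres (vectorised, recycled against `weight_kg`).
#' @return A factor with levels [bmi_levels()].
#' @examples
#' bmi_category(60, 1.65)
#' bmi_category(c(45, 95), 1.70)
#' @export
bmi_category <- function(weight_kg, height_m) {
  if (!is.numeric(weight_kg) || !is.numeric(height_m)) {
    stop("`weight_kg` and `height_m` must be numeric", call. = FALSE)
  }
  n <- max(length(weight_kg), length(height_m))
  weight_kg <- rep_len(weight_kg, n)
  height_m <- rep_len(height_m, n)
  bad <- !is.finite(weight_kg) | !is.finite(height_m) |
    weight_kg <= 0 | height_m <= 0
  if (any(bad)) {
    stop("weight and height must be finite and positive", call. = FALSE)
  }
  bmi <- weight_kg / height_m^2
  cut(bmi,
    breaks = c(0, 18.5, 25, 30, Inf),
    labels = bmi_levels(), right = FALSE
  )
}

#' IOM total weight-gain targets by BMI category
#'
#' Total-pregnancy gain recommendations (kg) per pre-pregnancy BMI category,
#' together with the first-trimester allowance used to anchor the weekly range
#' model at 13 weeks' gestation. The IOM assumes 0.5--2 kg gained by the end
#' of the first trimester for every category; both anchors are configurable so
#' that, e.g., a zero-gain anchor at 13 weeks can be expressed.
#'
#' @param first_trimester Length-2 numeric, kg gained by week 13 (min, max),
#'   applied to all categories.
#' @return A tibble with columns `bmi_category`, `total_min_kg`,
#'   `total_max_kg`, `ft_min_kg`, `ft_max_kg`; one row per category.
#' @export
iom_targets <- function(first_trimester = c(0.5, 2.0)) {
  stopifnot(is.numeric(first_trimester), length(first_trimester) == 2)
  out <- tibble::tibble(
    bmi_category = factor(bmi_levels(), levels = bmi_levels()),
    total_min_kg = c(12.5, 11.5, 7.0, 5.0),
    total_max_kg = c(18.0, 16.0, 11.5, 9.0),
    ft_min_kg = first_trimester[1],
    ft_max_kg = first_trimester[2]
  )
  validate_targets(out)
  out
}

validate_targets <- function(targets) {
  req <- c(
    "bmi_category", "total_min_kg", "total_max_kg",
    "ft_min_kg", "ft_max_kg"
  )
  if (!all(req %in% names(targets))) {
    stop("targets must have columns ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  cats <- as.character(targets$bmi_category)
  if (anyDuplicated(cats) || !setequal(cats, bmi_levels())) {
    stop("targets must contain each BMI category exactly once", call. = FALSE)
  }
  with(targets, {
    if (any(total_min_kg >= total_max_kg)) {
      stop("total_min_kg must be < total_max_kg", call. = FALSE)
    }
    if (any(ft_min_kg > ft_max_kg)) {
      stop("ft_min_kg must be <= ft_max_kg", call. = FALSE)
    }
    if (any(ft_max_kg >= total_min_kg)) {
      stop("first-trimester allowance must sit below the total target",
        call. = FALSE
      )
    }
  })
  invisible(targets)
}

# Core linear range: anchor (13 wk, first-trimester allowance) to
# (40 wk, total target), each bound interpolated independently.
range_at_week <- function(week, total_min, total_max, ft_min, ft_max) {
  f <- (week - 13) / 27
  list(
    min_kg = ft_min + f * (total_min - ft_min),
    max_kg = ft_max + f * (total_max - ft_max)
  )
}

#' Expected cumulative GWG range at a gestational week
#'
#' Linear interpolation between the first-trimester allowance anchored at
#' 13 weeks and the IOM total target at 40 weeks, applied independently to the
#' minimum and maximum bound. Fractional weeks are supported so a visit at the
#' actual (non-integer) gestational age can be scored.
#'
#' @param week Gestational week(s), in `[13, 40]`; fractional allowed.
#' @param category BMI category (character or factor, recycled).
#' @param targets Targets table from [iom_targets()].
#' @return A tibble with columns `bmi_category`, `week`, `min_kg`, `max_kg`.
#' @examples
#' weekly_range(40, "normal") # 11.5--16 kg, the IOM total
#' weekly_range(24, "obese")
#' @export
weekly_range <- function(week, category, targets = iom_targets()) {
  validate_targets(targets)
  if (!is.numeric(week) || any(!is.finite(week))) {
    stop("`week` must be finite numeric", call. = FALSE)
  }
  if (any(week < 13 | week > 40)) {
    stop("`week` must lie in [13, 40]; the range model is undefined in the ",
      "first trimester",
      call. = FALSE
    )
  }
  n <- max(length(week), length(category))
  week <- rep_len(week, n)
  category <- rep_len(as.character(category), n)
  idx <- match(category, as.character(targets$bmi_category))
  if (anyNA(idx)) {
    stop(
      "unknown BMI category: ",
      paste(unique(category[is.na(idx)]), collapse = ", "),
      call. = FALSE
    )
  }
  r <- range_at_week(
    week,
    targets$total_min_kg[idx], targets$total_max_kg[idx],
    targets$ft_min_kg[idx], targets$ft_max_kg[idx]
  )
  tibble::tibble(
    bmi_category = factor(category, levels = bmi_levels()),
    week = week,
    min_kg = r$min_kg,
    max_kg = r$max_kg
  )
}

#' Full weekly reference table
#'
#' One row per BMI category and integer gestational week 13--40 (4 x 28 =
#' 112 rows), each giving the expected minimum and maximum cumulative GWG.
#'
#' @inheritParams weekly_range
#' @param weeks Integer weeks to tabulate (default 13:40).
#' @return A tibble `bmi_category, week, min_kg, max_kg`, sorted by category
#'   then week.
#' @export
reference_table <- function(targets = iom_targets(), weeks = 13:40) {
  validate_targets(targets)
  grid <- tidyr::expand_grid(
    bmi_category = factor(bmi_levels(), levels = bmi_levels()),
    week = weeks
  )
  weekly_range(grid$week, grid$bmi_category, targets)
}

#' Write / read a reference table as CSV
#'
#' Plain CSV with header `bmi_category,week,min_kg,max_kg`, one row per
#' category-week.
#'
#' @param ref Tibble from [reference_table()].
#' @param path File path.
#' @return `write_reference_csv()` returns `ref` invisibly;
#'   `read_reference_csv()` returns the tibble.
#' @export
write_reference_csv <- function(ref, path) {
  readr::write_csv(ref, path)
  invisible(ref)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      bmi_category = readr::col_character(),
      week = readr::col_double(),
      min_kg = readr::col_double(),
      max_kg = readr::col_double()
    )
  )
  out$bmi_category <- factor(out$bmi_category, levels = bmi_levels())
  out
}
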