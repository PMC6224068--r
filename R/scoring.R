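#' Piecewise-linear component scorers
#'
#' The HEI-C 2010 scores every component by linear proration between a
#' minimum-score and a maximum-score standard, clamped to `[0, max_points]`.
#'
#' `score_adequacy()` handles upward-scored components: 0 points at or below
#' `standard_min`, `max_points` at or above `standard_max`, linear in
#' between. `score_fatty_acids()` is the adequacy scorer applied to the
#' (PUFA+MUFA)/SFA ratio with breakpoints 1.2 (0 points) and 2.5 (10 points).
#' `score_moderation()` handles downward-scored components:
#'
#' * `refined_grains`: a step — 10 points when less than 50% of grains are
#'   refined, 0 otherwise (the printed standards leave no interval between
#'   the max- and min-score thresholds). A linear variant with configurable
#'   breakpoints is available via `refined_breaks`.
#' * `empty_calories`: 20 points at <= 19% of energy, 0 at >= 50%, linear
#'   between.
#' * `sodium`: 10 points at or below the Adequate Intake (AI), sliding
#'   linearly to 8 points at the Tolerable Upper Intake Level (UL) and from 8
#'   to 0 between the UL and twice the UL; 0 beyond. This realizes the
#'   index's "8 to 10" maximum-point band for sodium.
#'
#' All scorers are vectorized.
#'
#' @param amount Component amount (servings/day for serving-based
#'   components).
#' @param standard_max,standard_min Amounts earning the maximum and minimum
#'   score.
#' @param max_points Maximum points for the component.
#' @param fat_ratio (PUFA + MUFA) / SFA ratio.
#' @param metric The moderation metric: percent of grains refined, mg sodium,
#'   or percent of energy from empty calories.
#' @param component One of `"refined_grains"`, `"sodium"`,
#'   `"empty_calories"`.
#' @param ai,ul Sodium Adequate Intake and Tolerable Upper Intake Level
#'   (mg/day) for the person's scoring group.
#' @param refined_breaks `NULL` for the printed step rule, or
#'   `c(max_standard, min_standard)` percentages for a linear variant.
#' @return Points in `[0, max_points]`.
#' @export
#' @examples
#' score_adequacy(2, standard_max = 4, standard_min = 0, max_points = 10)
#' score_fatty_acids(c(1.2, 1.85, 2.5))
#' score_moderation(34.5, "empty_calories")
score_adequacy <- function(amount, standard_max, standard_min, max_points) {
  if (any(amount < 0, na.rm = TRUE)) abort("adequacy amounts must be >= 0")
  prorate(amount, standard_max, standard_min, max_points)
}

# linear proration between standards, clamped; direction-agnostic
prorate <- function(amount, standard_max, standard_min, max_points) {
  pmin(pmax((amount - standard_min) / (standard_max - standard_min), 0), 1) *
    max_points
}

#' @rdname score_adequacy
#' @export
score_fatty_acids <- function(fat_ratio, standard_max = 2.5,
                              standard_min = 1.2, max_points = 10) {
  score_adequacy(fat_ratio, standard_max, standard_min, max_points)
}

#' @rdname score_adequacy
#' @export
score_moderation <- function(metric, component, ai = 1500, ul = 2300,
                             refined_breaks = NULL) {
  component <- match.arg(component,
                         c("refined_grains", "sodium", "empty_calories"))
  if (any(metric < 0, na.rm = TRUE)) abort("moderation metrics must be >= 0")
  switch(component,
    refined_grains = {
      if (is.null(refined_breaks)) {
        ifelse(metric < 50, 10, 0)
      } else {
        prorate(metric, refined_breaks[1], refined_breaks[2], 10)
      }
    },
    empty_calories = prorate(metric, 19, 50, 20),
    sodium = {
      upper <- prorate(metric, ai, ul, 2) + 8       # 10 -> 8 over AI..UL
      lower <- prorate(metric, ul, 2 * ul, 8)       # 8 -> 0 over UL..2UL
      ifelse(metric <= ul, upper, lower)
    }
  )
}

#' Aggregate recall days into per-person intake
#'
#' Implements the multi-day path of the NCI Simple Scoring Algorithm:
#' amounts and energy are summed across a person's valid recall days and the
#' score-relevant ratios are computed on the summed amounts (so each day
#' contributes in proportion to its energy). Ratios are total-based and thus
#' invariant to the number of days when days are identical.
#'
#' Degenerate denominators follow fixed total rules: all fat intakes zero
#' gives a fat ratio of 0; zero SFA with positive unsaturated fat gives an
#' infinite ratio (scores maximum points); zero total grains gives 0% refined
#' (no refined grains were consumed, so the moderation component scores full
#' points); zero summed energy marks the person invalid and is an error at
#' scoring time.
#'
#' @param records A recall tibble (see [generate_population()]) for one or
#'   more persons; only rows with `valid_recall = TRUE` contribute.
#' @return One row per person: identifiers, demographics, `n_days`, summed
#'   amounts, and derived `fat_ratio`, `pct_refined`, `pct_empty`.
#' @export
aggregate_person_intake <- function(records) {
  records <- filter(records, .data$valid_recall)
  if (nrow(records) == 0) abort("no valid recall days to aggregate")
  amount_cols <- c("energy_kcal", "total_veg_fruit", "whole_fruit",
                   "greens_beans", "whole_grains", "dairy", "total_protein",
                   "seafood_plant_protein", "refined_grains", "total_grains",
                   "pufa_g", "mufa_g", "sfa_g", "sodium_mg",
                   "empty_calorie_kcal")
  out <- records %>%
    group_by(.data$person_id, .data$survey_year, .data$age_years,
             .data$sex) %>%
    summarise(n_days = n(),
              across(all_of(amount_cols), sum),
              .groups = "drop")
  unsat <- out$pufa_g + out$mufa_g
  out$fat_ratio <- ifelse(out$sfa_g > 0, unsat / out$sfa_g,
                          ifelse(unsat > 0, Inf, 0))
  out$pct_refined <- ifelse(out$total_grains > 0,
                            100 * out$refined_grains / out$total_grains, 0)
  out$pct_empty <- ifelse(out$energy_kcal > 0,
                          100 * out$empty_calorie_kcal / out$energy_kcal, NA)
  out
}

#' Score persons with the HEI-C 2010
#'
#' `score_cohort()` scores every person in an aggregated intake table against
#' a standards table; `score_person()` is the single-person wrapper. The
#' scoring group (2-3, 4-8, 9-13 sex-combined; 14-18, 19-50, 51+ per sex) is
#' resolved from age and sex; serving amounts are divided by `n_days` so
#' multi-day persons are scored on their mean daily amounts while the
#' ratio-based components use the day-summed totals directly (the two paths
#' are equivalent for ratios).
#'
#' @param intake Output of [aggregate_person_intake()].
#' @param standards A standards table, see [default_hei_standards()].
#' @param basis `"absolute"` scores serving components against absolute
#'   servings/day; `"per_1000_kcal"` scores serving densities per 1000 kcal
#'   against the same standards reinterpreted as densities.
#' @return A tibble with `person_id`, `survey_year`, one column per component
#'   score, and `total` in `[0, 100]`.
#' @export
#' @examples
#' rec <- generate_population(generator_config(n_2004 = 50, n_2015 = 50,
#'                                             seed = 1))
#' sc <- score_cohort(aggregate_person_intake(rec$records))
#' range(sc$total)
score_cohort <- function(intake, standards = default_hei_standards(),
                         basis = c("absolute", "per_1000_kcal")) {
  basis <- match.arg(basis)
  validate_hei_standards(standards)
  if (any(intake$energy_kcal <= 0)) {
    abort("persons with zero summed energy are invalid and cannot be scored")
  }
  key <- scoring_group(intake$age_years, intake$sex)
  wide <- standards %>%
    select("component", "group", "sex", "max_points", "standard_max",
           "standard_min") %>%
    tidyr::pivot_wider(names_from = "component",
                       values_from = c("max_points", "standard_max",
                                       "standard_min"))
  idx <- match(paste(key$group, key$sex),
               paste(wide$group, wide$sex))
  if (anyNA(idx)) {
    miss <- unique(paste(key$group, key$sex)[is.na(idx)])
    abort(paste0("standards table has no row for scoring group(s): ",
                 paste(miss, collapse = ", ")))
  }
  std <- wide[idx, ]

  serving <- c("total_veg_fruit", "whole_fruit", "greens_beans",
               "whole_grains", "dairy", "total_protein",
               "seafood_plant_protein")
  denom <- if (basis == "absolute") intake$n_days else
    intake$energy_kcal / 1000
  scores <- tibble(person_id = intake$person_id,
                   survey_year = intake$survey_year)
  for (comp in serving) {
    scores[[comp]] <- score_adequacy(
      intake[[comp]] / denom,
      std[[paste0("standard_max_", comp)]],
      std[[paste0("standard_min_", comp)]],
      std[[paste0("max_points_", comp)]])
  }
  scores$fatty_acids <- score_fatty_acids(
    intake$fat_ratio,
    std$standard_max_fatty_acids, std$standard_min_fatty_acids,
    std$max_points_fatty_acids)
  scores$refined_grains <- score_moderation(intake$pct_refined,
                                            "refined_grains")
  scores$sodium <- score_moderation(
    intake$sodium_mg / intake$n_days, "sodium",
    ai = std$standard_max_sodium, ul = std$standard_min_sodium / 2)
  scores$empty_calories <- score_moderation(intake$pct_empty,
                                            "empty_calories")
  scores$total <- rowSums(as.matrix(scores[, hei_components()]))
  scores
}

#' @rdname score_cohort
#' @export
score_person <- function(intake, standards = default_hei_standards(),
                         basis = c("absolute", "per_1000_kcal")) {
  if (nrow(intake) != 1) abort("score_person() expects a single person row")
  score_cohort(intake, standards, basis)
}
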