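#' HEI-C 2010 scoring standards
#'
#' The HEI-C 2010 scores a diet on 11 components — 8 adequacy components
#' (total vegetables and fruit, whole fruit, greens and beans, whole grains,
#' dairy, total protein foods, seafood and plant proteins, fatty acids) and 3
#' moderation components (refined grains, sodium, empty calories) — summing to
#' a 0-100 total (adequacy 60 + moderation 40). Serving standards depend on
#' the age/sex scoring group of Canada's Food Guide: children 2-3, 4-8 and
#' 9-13 years are scored sex-combined; 14-18, 19-50 and 51+ years are scored
#' per sex.
#'
#' `default_hei_standards()` returns the standards table shipped with the
#' package. The published index prints each serving standard as a range
#' spanning the food-guide groups (e.g. 4-10 servings of vegetables and
#' fruit); the shipped table resolves each group to a scalar inside that
#' range, with young children at the low end and adult males at the high end.
#' These per-group scalars follow the 2007 food-guide recommended servings
#' and are editable: any table with the same columns is accepted by the
#' scoring functions.
#'
#' Sodium is scored against the group's Adequate Intake (AI) and Tolerable
#' Upper Intake Level (UL) in mg/day: 10 points at or below the AI, sliding
#' to 8 points at the UL and to 0 at twice the UL.
#'
#' @return A tibble with columns `component`, `group`, `sex` (`"both"` for the
#'   sex-combined child groups), `max_points`, `standard_max`, `standard_min`,
#'   `kind` (`"adequacy"`/`"moderation"`) and `basis`.
#' @export
#' @examples
#' std <- default_hei_standards()
#' sum(std$max_points[std$sex %in% c("both", "male") & std$group_rank == 1])
default_hei_standards <- function() {
  groups <- tibble(
    group = c("2-3", "4-8", "9-13",
              "14-18", "14-18", "19-50", "19-50", "51+", "51+"),
    sex   = c("both", "both", "both",
              "female", "male", "female", "male", "female", "male"),
    veg_fruit   = c(4,   5,   6,   7,    8,    7.5,  10,   7,    7),
    whole_grain = c(1.5, 2,   3,   3,    3.5,  3,    4,    3,    3.5),
    dairy       = c(2,   2,   3.5, 3.5,  3.5,  2,    2,    3,    3),
    protein     = c(1,   1,   1.5, 2,    3,    2,    3,    2,    3),
    sodium_ai   = c(1000, 1200, 1500, 1500, 1500, 1500, 1500, 1300, 1300),
    sodium_ul   = c(1500, 1900, 2200, 2300, 2300, 2300, 2300, 2300, 2300)
  )
  comp <- function(component, max_points, standard_max, standard_min,
                   kind, basis) {
    tibble(component = component, group = groups$group, sex = groups$sex,
           max_points = max_points, standard_max = standard_max,
           standard_min = standard_min, kind = kind, basis = basis)
  }
  out <- bind_rows(
    comp("total_veg_fruit", 10, groups$veg_fruit, 0,
         "adequacy", "absolute_servings"),
    # whole fruit and greens/beans scale with the vegetable-and-fruit
    # standard: printed ranges 0.84-2.1 and 0.42-1.05 are 0.21x and 0.105x
    # the 4-10 serving range
    comp("whole_fruit", 5, 0.21 * groups$veg_fruit, 0,
         "adequacy", "absolute_servings"),
    comp("greens_beans", 5, 0.105 * groups$veg_fruit, 0,
         "adequacy", "absolute_servings"),
    comp("whole_grains", 10, groups$whole_grain, 0,
         "adequacy", "absolute_servings"),
    comp("dairy", 10, groups$dairy, 0, "adequacy", "absolute_servings"),
    comp("total_protein", 5, groups$protein, 0,
         "adequacy", "absolute_servings"),
    comp("seafood_plant_protein", 5, 0.32 * groups$protein, 0,
         "adequacy", "absolute_servings"),
    comp("fatty_acids", 10, 2.5, 1.2, "adequacy", "fat_ratio"),
    comp("refined_grains", 10, 50, 50, "moderation", "percent_grains"),
    comp("sodium", 10, groups$sodium_ai, 2 * groups$sodium_ul,
         "moderation", "sodium_band"),
    comp("empty_calories", 20, 19, 50, "moderation", "percent_energy")
  )
  # sodium UL is implied by the table: standard_min is 2 x UL
  out <- out %>%
    mutate(group_rank = match(.data$group, c("2-3", "4-8", "9-13",
                                             "14-18", "19-50", "51+")))
  validate_hei_standards(out)
  out
}

#' @rdname default_hei_standards
#' @param path Path to a standards CSV with the columns documented above.
#' @export
read_hei_standards <- function(path) {
  std <- readr::read_csv(path, show_col_types = FALSE)
  std <- as_tibble(std)
  if (!"group_rank" %in% names(std)) {
    std$group_rank <- match(std$group, c("2-3", "4-8", "9-13",
                                         "14-18", "19-50", "51+"))
  }
  validate_hei_standards(std)
  std
}

hei_components <- function() {
  c("total_veg_fruit", "whole_fruit", "greens_beans", "whole_grains",
    "dairy", "total_protein", "seafood_plant_protein", "fatty_acids",
    "refined_grains", "sodium", "empty_calories")
}

validate_hei_standards <- function(std) {
  need <- c("component", "group", "sex", "max_points", "standard_max",
            "standard_min", "kind", "basis")
  missing <- setdiff(need, names(std))
  if (length(missing)) {
    abort(paste0("standards table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!setequal(unique(std$component), hei_components())) {
    abort("standards table must cover exactly the 11 HEI-C 2010 components")
  }
  # each (group, sex) cell must total 100 points: adequacy 60 + moderation 40
  tot <- std %>%
    group_by(.data$group, .data$sex, .data$kind) %>%
    summarise(pts = sum(.data$max_points), .groups = "drop")
  bad <- tot$pts[tot$kind == "adequacy"] != 60 |
    tot$pts[tot$kind == "moderation"] != 40
  if (any(bad)) abort("component max points must sum to 60 adequacy + 40 moderation per group")
  adequacy <- std$kind == "adequacy"
  if (any(std$standard_max[adequacy] <= std$standard_min[adequacy])) {
    abort("adequacy standards must have standard_max > standard_min")
  }
  mod <- std$kind == "moderation" & std$component != "refined_grains"
  if (any(std$standard_min[mod] <= std$standard_max[mod])) {
    abort("moderation standards must have standard_min > standard_max (reversed direction)")
  }
  invisible(std)
}

#' Age/sex crosswalks for scoring and cost strata
#'
#' `scoring_group()` maps age in whole years to the food-guide scoring group
#' used by the HEI-C 2010 standards (2-3, 4-8 and 9-13 sex-combined; 14-18,
#' 19-50 and 51+ sex-specific). `cost_age_group()` maps age to the six
#' age strata used for cost attribution (<15, 15-34, 35-54, 55-64, 65-74,
#' 75+).
#'
#' @param age_years Integer vector of ages in whole years.
#' @param sex Character vector, `"male"` or `"female"` (recycled).
#' @return `scoring_group()`: a tibble with columns `group` and `sex`
#'   (`"both"` for child groups); `cost_age_group()`: a character vector.
#' @export
#' @examples
#' scoring_group(c(2, 7, 12, 16, 30, 70), "female")
#' cost_age_group(c(2, 20, 40, 60, 70, 80))
scoring_group <- function(age_years, sex) {
  if (any(age_years < 2, na.rm = TRUE)) {
    abort("scoring groups are defined for ages >= 2 years")
  }
  grp <- cut(age_years, c(2, 4, 9, 14, 19, 51, Inf), right = FALSE,
             labels = c("2-3", "4-8", "9-13", "14-18", "19-50", "51+"))
  grp <- as.character(grp)
  sex <- rep_len(as.character(sex), length(age_years))
  tibble(group = grp,
         sex = ifelse(grp %in% c("2-3", "4-8", "9-13"), "both", sex))
}

#' @rdname scoring_group
#' @export
cost_age_group <- function(age_years) {
  as.character(cut(age_years, c(-Inf, 15, 35, 55, 65, 75, Inf), right = FALSE,
                   labels = c("<15", "15-34", "35-54", "55-64",
                              "65-74", "75+")))
}

cost_age_levels <- function() {
  c("<15", "15-34", "35-54", "55-64", "65-74", "75+")
}
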