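test_that("component scorers hit the printed breakpoints exactly", {
  # adequacy: whole grains against a standard of 4 servings
  expect_identical(score_adequacy(0, 4, 0, 10), 0)
  expect_identical(score_adequacy(4, 4, 0, 10), 10)
  expect_identical(score_adequacy(2, 4, 0, 10), 5)
  expect_identical(score_adequacy(9, 4, 0, 10), 10)  # clamped above
  expect_error(score_adequacy(-1, 4, 0, 10), ">= 0")

  # fatty acids: (PUFA+MUFA)/SFA, 1.2 -> 0 and 2.5 -> 10, linear between
  expect_equal(score_fatty_acids(c(2.5, 1.2, 1.85, 0, 10, Inf)),
               c(10, 0, 5, 0, 10, 10))

  # empty calories: <=19% of energy -> 20, >=50% -> 0
  expect_equal(score_moderation(c(19, 50, 34.5, 0, 80), "empty_calories"),
               c(20, 0, 10, 20, 0))

  # sodium band: AI -> 10, UL -> 8, 2xUL -> 0
  expect_equal(
    score_moderation(c(1500, 2300, 4600, 0, 1900, 3450, 9999), "sodium",
                     ai = 1500, ul = 2300),
    c(10, 8, 0, 10, 9, 4, 0))

  # refined grains: step at 50% of grains refined
  expect_equal(score_moderation(c(49.999, 50, 0, 100), "refined_grains"),
               c(10, 0, 10, 0))
  # linear variant with configurable breakpoints
  expect_equal(score_moderation(50, "refined_grains",
                                refined_breaks = c(40, 60)), 5)
})

test_that("piecewise-linear scorers agree with interpolation through the printed breakpoints", {
  grid <- seq(0, 6000, by = 7.3)
  # independent oracle: linear interpolation through the breakpoints
  ora <- function(x, xs, ys) approx(xs, ys, xout = x, rule = 2)$y
  expect_equal(score_fatty_acids(grid / 1000),
               ora(grid / 1000, c(1.2, 2.5), c(0, 10)), tolerance = 1e-12)
  expect_equal(score_moderation(grid / 60, "empty_calories"),
               ora(grid / 60, c(19, 50), c(20, 0)), tolerance = 1e-12)
  expect_equal(score_moderation(grid, "sodium", ai = 1500, ul = 2300),
               ora(grid, c(1500, 2300, 4600), c(10, 8, 0)),
               tolerance = 1e-12)
})

test_that("person intake aggregation sums days and derives total-based ratios", {
  one <- make_recall()
  agg <- aggregate_person_intake(one)
  expect_equal(agg$energy_kcal, one$energy_kcal)
  expect_equal(agg$whole_grains, one$whole_grains)
  expect_equal(agg$n_days, 1L)

  # two identical days: ratios equal the single-day ratios
  two <- dplyr::bind_rows(one, dplyr::mutate(one, day_index = 2L))
  agg2 <- aggregate_person_intake(two)
  expect_equal(agg2$fat_ratio, agg$fat_ratio)
  expect_equal(agg2$pct_refined, agg$pct_refined)
  expect_equal(agg2$pct_empty, agg$pct_empty)
  expect_equal(agg2$energy_kcal, 2 * agg$energy_kcal)

  # days with (PUFA+MUFA, SFA) of (10,10) then (30,10) -> ratio 40/20 = 2
  days <- dplyr::bind_rows(
    make_recall(pufa_g = 4, mufa_g = 6, sfa_g = 10),
    make_recall(day_index = 2L, pufa_g = 12, mufa_g = 18, sfa_g = 10))
  expect_equal(aggregate_person_intake(days)$fat_ratio, 2)

  expect_error(aggregate_person_intake(make_recall(valid_recall = FALSE)),
               "no valid recall")
})

test_that("a person meeting every standard scores the printed maximum vector", {
  std <- default_hei_standards()
  # adult male 19-50: group standards from the shipped table
  at <- std[std$group == "19-50" & std$sex == "male", ]
  get <- function(comp, col = "standard_max") {
    at[[col]][at$component == comp]
  }
  rec <- make_recall(
    sex = "male", age_years = 30L,
    total_veg_fruit = get("total_veg_fruit"),
    whole_fruit = get("whole_fruit"),
    greens_beans = get("greens_beans"),
    whole_grains = get("whole_grains"), dairy = get("dairy"),
    total_protein = get("total_protein"),
    seafood_plant_protein = get("seafood_plant_protein"),
    pufa_g = 25, mufa_g = 25, sfa_g = 20,      # ratio 2.5
    refined_grains = 0, total_grains = get("whole_grains"),
    sodium_mg = get("sodium"),                 # at the AI
    empty_calorie_kcal = 0.19 * 2000)          # 19% of energy
  sc <- score_person(aggregate_person_intake(rec))
  comps <- c("total_veg_fruit", "whole_fruit", "greens_beans",
             "whole_grains", "dairy", "total_protein",
             "seafood_plant_protein", "fatty_acids", "refined_grains",
             "sodium", "empty_calories")
  expect_equal(unname(unlist(sc[comps])),
               c(10, 5, 5, 10, 10, 5, 5, 10, 10, 10, 20))
  expect_equal(sc$total, 100)
})

test_that("all-zero intake scores only the zero-intake moderation points", {
  rec <- make_recall(total_veg_fruit = 0, whole_fruit = 0, greens_beans = 0,
                     whole_grains = 0, dairy = 0, total_protein = 0,
                     seafood_plant_protein = 0, refined_grains = 0,
                     total_grains = 0, pufa_g = 0, mufa_g = 0, sfa_g = 0,
                     sodium_mg = 0, empty_calorie_kcal = 0)
  sc <- score_person(aggregate_person_intake(rec))
  expect_equal(sc$sodium, 10)
  expect_equal(sc$empty_calories, 20)
  expect_equal(sc$refined_grains, 10)   # no grains consumed at all
  expect_equal(sc$fatty_acids, 0)       # all fats zero
  expect_equal(sc$total, 40)
})

test_that("scores are monotone, ratio-scale invariant, and bounded in [0,100]", {
  intake <- random_intakes(200, seed = 42)
  sc <- score_cohort(intake)
  expect_true(all(sc$total >= 0 & sc$total <= 100))
  expect_equal(sc$total, rowSums(as.matrix(
    sc[, setdiff(names(sc), c("person_id", "survey_year", "total"))])),
    tolerance = 1e-9)

  # monotonicity: raising an adequacy amount never lowers its score;
  # raising a moderation metric never raises its score
  bump <- intake
  bump$whole_grains <- bump$whole_grains + 1
  expect_true(all(score_cohort(bump)$whole_grains >= sc$whole_grains))
  worse <- intake
  worse$sodium_mg <- worse$sodium_mg * 1.5
  expect_true(all(score_cohort(worse)$sodium <= sc$sodium))
  worse <- dplyr::mutate(intake,
                         empty_calorie_kcal = pmin(empty_calorie_kcal * 1.4,
                                                   energy_kcal),
                         pct_empty = 100 * empty_calorie_kcal / energy_kcal)
  expect_true(all(score_cohort(worse)$empty_calories <=
                    sc$empty_calories))

  # doubling all amounts and energy leaves ratio-based components unchanged
  dbl <- intake
  amt <- c("energy_kcal", "pufa_g", "mufa_g", "sfa_g", "refined_grains",
           "whole_grains", "total_grains", "empty_calorie_kcal")
  dbl[amt] <- dbl[amt] * 2
  dbl$fat_ratio <- (dbl$pufa_g + dbl$mufa_g) / dbl$sfa_g
  dbl$pct_refined <- 100 * dbl$refined_grains / dbl$total_grains
  dbl$pct_empty <- 100 * dbl$empty_calorie_kcal / dbl$energy_kcal
  sc2 <- score_cohort(dbl)
  expect_equal(sc2$fatty_acids, sc$fatty_acids)
  expect_equal(sc2$refined_grains, sc$refined_grains)
  expect_equal(sc2$empty_calories, sc$empty_calories)
})

test_that("scoring groups and standards resolve by age and sex", {
  key <- scoring_group(c(2, 5, 10, 15, 30, 60), "male")
  expect_equal(key$group, c("2-3", "4-8", "9-13", "14-18", "19-50", "51+"))
  expect_equal(key$sex, c("both", "both", "both", "male", "male", "male"))
  expect_error(scoring_group(1, "male"), ">= 2")
  expect_equal(cost_age_group(c(2, 14, 15, 34, 35, 64, 74, 75)),
               c("<15", "<15", "15-34", "15-34", "35-54", "55-64",
                 "65-74", "75+"))

  # a standards table missing a group errors with the group named
  std <- default_hei_standards()
  expect_error(
    score_cohort(aggregate_person_intake(make_recall(age_years = 70L)),
                 std[!(std$group == "51+" & std$sex == "female"), ]),
    "51\\+ female")
  expect_error(score_cohort(
    dplyr::mutate(aggregate_person_intake(make_recall()),
                  energy_kcal = 0)), "zero summed energy")
})
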