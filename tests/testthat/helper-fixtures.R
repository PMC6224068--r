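# Builders for small hand-constructed fixtures used across the suite.

# one recall record row with sensible adult defaults; override any field
make_recall <- function(person_id = "p1", survey_year = 2004L,
                        age_years = 30L, sex = "female", day_index = 1L,
                        energy_kcal = 2000, total_veg_fruit = 5,
                        whole_fruit = 1, greens_beans = 0.5,
                        whole_grains = 2, dairy = 2, total_protein = 2,
                        seafood_plant_protein = 0.5, refined_grains = 2,
                        total_grains = 4, pufa_g = 10, mufa_g = 15,
                        sfa_g = 20, sodium_mg = 2000,
                        empty_calorie_kcal = 400, pregnant = FALSE,
                        breastmilk_only = FALSE, valid_recall = TRUE) {
  tibble::tibble(person_id = person_id, survey_year = survey_year,
                 age_years = age_years, sex = sex, day_index = day_index,
                 energy_kcal = energy_kcal,
                 total_veg_fruit = total_veg_fruit,
                 whole_fruit = whole_fruit, greens_beans = greens_beans,
                 whole_grains = whole_grains, dairy = dairy,
                 total_protein = total_protein,
                 seafood_plant_protein = seafood_plant_protein,
                 refined_grains = refined_grains,
                 total_grains = total_grains, pufa_g = pufa_g,
                 mufa_g = mufa_g, sfa_g = sfa_g, sodium_mg = sodium_mg,
                 empty_calorie_kcal = empty_calorie_kcal,
                 pregnant = pregnant, breastmilk_only = breastmilk_only,
                 valid_recall = valid_recall)
}

# a stratified two-PSU design table for BRR tests: one unit per PSU
make_strata_design <- function(n_strata, weights = NULL) {
  n <- 2L * n_strata
  tibble::tibble(person_id = seq_len(n),
                 weight = if (is.null(weights)) rep(1, n) else weights,
                 stratum = rep(seq_len(n_strata), each = 2),
                 psu = rep(c(1L, 2L), n_strata))
}

# random person-level intake rows for property tests
random_intakes <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    person_id = paste0("r", seq_len(n)), survey_year = 2004L,
    age_years = sample(2:90, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    n_days = 1L,
    energy_kcal = runif(n, 500, 4000),
    total_veg_fruit = runif(n, 0, 15), whole_fruit = runif(n, 0, 4),
    greens_beans = runif(n, 0, 2), whole_grains = runif(n, 0, 6),
    dairy = runif(n, 0, 6), total_protein = runif(n, 0, 5),
    seafood_plant_protein = runif(n, 0, 2),
    refined_grains = runif(n, 0, 8), total_grains = NA_real_,
    pufa_g = runif(n, 0, 30), mufa_g = runif(n, 0, 40),
    sfa_g = runif(n, 0, 40), sodium_mg = runif(n, 0, 6000),
    empty_calorie_kcal = NA_real_,
    fat_ratio = NA_real_, pct_refined = NA_real_, pct_empty = NA_real_
  ) |>
    dplyr::mutate(
      total_grains = refined_grains + whole_grains,
      empty_calorie_kcal = runif(n, 0, 1) * energy_kcal,
      fat_ratio = ifelse(sfa_g > 0, (pufa_g + mufa_g) / sfa_g, Inf),
      pct_refined = ifelse(total_grains > 0,
                           100 * refined_grains / total_grains, 0),
      pct_empty = 100 * empty_calorie_kcal / energy_kcal)
}

# brute-force weighted type-1 quantile: scan the sorted unique values of x
# and return the first whose accumulated weight share reaches p
oracle_weighted_quantile <- function(x, w, p) {
  ux <- sort(unique(x))
  share <- vapply(ux, function(v) sum(w[x <= v]) / sum(w), numeric(1))
  ux[which(share >= p - 1e-12)[1]]
}

# termwise brute-force PAF, written as an explicit loop
oracle_paf <- function(p, rr, e = c(-3.5, -2.5, -1.5, -0.5)) {
  s <- 0
  for (i in 1:4) s <- s + p[i] * (rr^e[i] - 1)
  s / (1 + s)
}
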