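#' Configuration for the synthetic nutrition-survey cohort
#'
#' Builds the parameter set for [generate_population()]. The generator
#' emulates two cross-sectional nutrition-survey cycles (2004 and 2015) of
#' 24-hour dietary recalls: respondent counts per cycle, an age/sex
#' structure over the food-guide scoring groups, stratified sampling weights
#' with BRR replicate weights, a second-recall subsample, and a small
#' fraction of records that downstream exclusion rules must remove
#' (children under 2 years, pregnant respondents, breast-milk-only infants,
#' invalid recalls).
#'
#' Intake components are drawn from independent gamma distributions per
#' (year, sex, scoring group) whose means are tied to a shared person-level
#' latent "diet quality" factor, which induces realistic correlation between
#' components and lets a single `quality_shift` move the whole score
#' distribution between survey years. Second recall days redraw day-level
#' amounts around the same person-level means.
#'
#' Default respondent counts and second-recall fractions follow the 2004 and
#' 2015 Canadian nutrition-survey cycles (35,107 and 20,487 respondents;
#' 30.7% and 37% with a second recall); intake distribution parameters are
#' package choices producing realistic score spreads.
#'
#' @param n_2004,n_2015 Respondents per survey year.
#' @param quality_shift Additive 2015 shift of the latent quality factor
#'   (standard-deviation units); 0 makes the two years exchangeable.
#' @param second_recall_frac Named fractions of respondents with a second
#'   recall day, per year.
#' @param exclusion_rates Named rates for generated-to-be-excluded records:
#'   `under2`, `pregnant`, `breastmilk_only`, `invalid`.
#' @param pop_totals Named population totals used to scale sampling weights.
#' @param fay_rho Fay factor for the BRR replicate weights.
#' @param n_replicates Number of BRR replicates (default 500).
#' @param seed Integer random seed; fixed seed gives byte-identical output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_2004 = 35107, n_2015 = 20487,
                             quality_shift = 0.35,
                             second_recall_frac = c("2004" = 0.307,
                                                    "2015" = 0.37),
                             exclusion_rates = c(under2 = 0.008,
                                                 pregnant = 0.01,
                                                 breastmilk_only = 0.003,
                                                 invalid = 0.012),
                             pop_totals = c("2004" = 31e6, "2015" = 35e6),
                             fay_rho = 0, n_replicates = 500,
                             seed = 1L) {
  # population share per scoring group (within each sex); rough Canadian
  # age pyramid collapsed onto the food-guide groups
  group_shares <- c("2-3" = 0.025, "4-8" = 0.06, "9-13" = 0.065,
                    "14-18" = 0.07, "19-50" = 0.44, "51+" = 0.34)
  stopifnot(abs(sum(group_shares) - 1) < 1e-9)
  cfg <- list(
    n = c("2004" = as.integer(n_2004), "2015" = as.integer(n_2015)),
    quality_shift = quality_shift,
    second_recall_frac = second_recall_frac,
    exclusion_rates = exclusion_rates,
    pop_totals = pop_totals,
    group_shares = group_shares,
    fay_rho = fay_rho,
    n_replicates = as.integer(n_replicates),
    pseudo_strata = 8L,   # design strata per (year, sex, group) cell
    # person-level latent quality: q ~ N(year_mean, 1); component means are
    # mean_scale x group standard x exp(quality_loading x q)
    quality_loading = 0.35,
    mean_scale = c(total_veg_fruit = 0.75, whole_fruit = 0.65,
                   greens_beans = 0.55, whole_grains = 0.6, dairy = 0.7,
                   total_protein = 0.9, seafood_plant_protein = 0.55),
    gamma_shape = 4,          # day-level gamma shape for serving components
    day_noise_sd = 0.2,       # lognormal day-to-day multiplier on means
    energy_mean = c("2-3" = 1300, "4-8" = 1700, "9-13" = 2000,
                    "14-18" = 2300, "19-50" = 2300, "51+" = 2000),
    energy_male_factor = 1.15,
    energy_shape = 25,
    sfa_mean = 25, sfa_shape = 9,
    fat_ratio_log_mean = log(1.6), fat_ratio_loading = 0.25,
    fat_ratio_log_sd = 0.3,
    sodium_mean = 2800, sodium_loading = -0.15, sodium_shape = 8,
    refined_logit_mean = 0.25, refined_loading = -0.5, refined_sd = 0.6,
    empty_logit_mean = -0.85, empty_loading = -0.4, empty_sd = 0.5,
    weight_jitter_sd = 0.3,
    seed = as.integer(seed))
  if (any(unlist(cfg$mean_scale) <= 0) || cfg$gamma_shape <= 0 ||
      any(cfg$pop_totals <= 0)) {
    abort("invalid generator configuration: non-positive scale parameter")
  }
  if (any(second_recall_frac < 0 | second_recall_frac > 1)) {
    abort("second_recall_frac must be in [0, 1]")
  }
  class(cfg) <- "generator_config"
  cfg
}

#' Generate a synthetic two-cycle recall cohort with survey design
#'
#' Draws the full synthetic cohort described by a [generator_config()]:
#' one row per person-day of dietary recall plus a stratified survey design
#' (strata are year x sex x scoring group, two half-sample PSUs per stratum)
#' with BRR replicate weights.
#'
#' @param config A [generator_config()].
#' @return A list with `records` (recall tibble, one row per person-day),
#'   `design` (a `survey_design`, see [brr_replicate_weights()]), and
#'   `strata` (per-person stratum/PSU assignments).
#' @export
#' @examples
#' pop <- generate_population(generator_config(n_2004 = 100, n_2015 = 100))
#' nrow(pop$records) >= 200
generate_population <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (any(unlist(config$mean_scale) <= 0) || config$gamma_shape <= 0 ||
      config$energy_shape <= 0 || config$sodium_shape <= 0 ||
      config$sfa_shape <= 0 || any(config$pop_totals <= 0)) {
    abort("invalid generator configuration: non-positive scale parameter")
  }
  set.seed(config$seed)
  groups <- names(config$group_shares)
  age_lo <- c("2-3" = 2, "4-8" = 4, "9-13" = 9, "14-18" = 14,
              "19-50" = 19, "51+" = 51)
  age_hi <- c("2-3" = 3, "4-8" = 8, "9-13" = 13, "14-18" = 18,
              "19-50" = 50, "51+" = 90)
  std <- default_hei_standards()

  persons <- lapply(names(config$n), function(yr) {
    n <- config$n[[yr]]
    grp <- sample(groups, n, replace = TRUE, prob = config$group_shares)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    age <- floor(runif(n, age_lo[grp], age_hi[grp] + 1))
    # records destined for the exclusion filter
    under2 <- runif(n) < config$exclusion_rates[["under2"]]
    age[under2] <- sample(0:1, sum(under2), replace = TRUE)
    pregnant <- sex == "female" & age >= 15 & age <= 49 &
      runif(n) < config$exclusion_rates[["pregnant"]] / 0.25
    breastmilk <- age < 2 | runif(n) < config$exclusion_rates[["breastmilk_only"]] * (age <= 2)
    breastmilk <- under2 & breastmilk
    invalid <- runif(n) < config$exclusion_rates[["invalid"]]
    q <- rnorm(n, mean = if (yr == "2015") config$quality_shift else 0, 1)
    tibble(person_id = paste0(yr, "-", seq_len(n)), survey_year = as.integer(yr),
           age_years = as.integer(age), sex = sex, group = grp, quality = q,
           pregnant = pregnant, breastmilk_only = breastmilk,
           invalid = invalid,
           second = runif(n) < config$second_recall_frac[[yr]])
  }) %>% bind_rows()

  # person-level expected daily amounts from group standards and latent quality
  skey <- ifelse(persons$group %in% c("2-3", "4-8", "9-13"), "both",
                 persons$sex)
  std_wide <- std %>%
    select("component", "group", "sex", "standard_max") %>%
    tidyr::pivot_wider(names_from = "component",
                       values_from = "standard_max")
  sidx <- match(paste(persons$group, skey),
                paste(std_wide$group, std_wide$sex))
  qfac <- exp(config$quality_loading * persons$quality)
  mu <- lapply(names(config$mean_scale), function(comp) {
    config$mean_scale[[comp]] * std_wide[[comp]][sidx] * qfac
  })
  names(mu) <- names(config$mean_scale)
  mu$energy <- config$energy_mean[persons$group] *
    ifelse(persons$sex == "male", config$energy_male_factor, 1)
  mu$sodium <- config$sodium_mean *
    exp(config$sodium_loading * persons$quality)
  mu$fat_ratio <- exp(config$fat_ratio_log_mean +
                        config$fat_ratio_loading * persons$quality +
                        rnorm(nrow(persons), 0, config$fat_ratio_log_sd))
  mu$refined_frac <- plogis(config$refined_logit_mean +
                              config$refined_loading * persons$quality +
                              rnorm(nrow(persons), 0, config$refined_sd))
  mu$empty_frac <- plogis(config$empty_logit_mean +
                            config$empty_loading * persons$quality +
                            rnorm(nrow(persons), 0, config$empty_sd))

  draw_days <- function(day_index) {
    who <- if (day_index == 1) rep(TRUE, nrow(persons)) else persons$second
    idx <- which(who)
    m <- length(idx)
    dn <- function(x) x[idx] * rlnorm(m, -config$day_noise_sd^2 / 2,
                                      config$day_noise_sd)
    gam <- function(mean, shape) rgamma(m, shape, rate = shape / mean)
    rec <- tibble(
      person_id = persons$person_id[idx], day_index = day_index,
      energy_kcal = gam(dn(mu$energy), config$energy_shape))
    for (comp in names(config$mean_scale)) {
      rec[[comp]] <- gam(dn(mu[[comp]]), config$gamma_shape)
    }
    whole <- rec$whole_grains
    refined <- whole * mu$refined_frac[idx] / (1 - mu$refined_frac[idx])
    rec$refined_grains <- refined
    rec$total_grains <- whole + refined
    rec$sfa_g <- gam(dn(rep(config$sfa_mean, nrow(persons))),
                     config$sfa_shape)
    unsat <- rec$sfa_g * mu$fat_ratio[idx]
    rec$pufa_g <- 0.4 * unsat
    rec$mufa_g <- 0.6 * unsat
    rec$sodium_mg <- gam(dn(mu$sodium), config$sodium_shape)
    rec$empty_calorie_kcal <- pmin(mu$empty_frac[idx], 0.95) *
      rec$energy_kcal
    rec
  }
  records <- bind_rows(draw_days(1), draw_days(2)) %>%
    left_join(persons %>%
                select("person_id", "survey_year", "age_years", "sex",
                       "pregnant", "breastmilk_only", "invalid"),
              by = "person_id") %>%
    mutate(valid_recall = !.data$invalid) %>%
    select(-"invalid") %>%
    arrange(.data$person_id, .data$day_index)

  # survey design: each (year, sex, scoring group) cell is carved into
  # several pseudo-strata of paired half-sample PSUs, mimicking the many
  # design strata of a national survey; this is what gives the BRR variance
  # estimator its degrees of freedom
  persons <- persons %>%
    group_by(.data$survey_year, .data$sex, .data$group) %>%
    mutate(pseudo = sample(rep_len(seq_len(config$pseudo_strata), n()))) %>%
    ungroup() %>%
    mutate(stratum = as.integer(factor(paste(.data$survey_year, .data$sex,
                                             .data$group, .data$pseudo))),
           psu = sample(c(1L, 2L), n(), replace = TRUE))
  cell_n <- persons %>% count(.data$survey_year, .data$group, .data$sex)
  persons <- persons %>%
    left_join(cell_n, by = c("survey_year", "group", "sex")) %>%
    mutate(weight = config$pop_totals[as.character(.data$survey_year)] *
             config$group_shares[.data$group] / 2 / .data$n *
             rlnorm(n(), -config$weight_jitter_sd^2 / 2,
                    config$weight_jitter_sd))
  design <- brr_replicate_weights(
    persons %>% select("person_id", "weight", "stratum", "psu"),
    R = config$n_replicates, fay_rho = config$fay_rho)
  list(records = records, design = design,
       strata = persons %>% select("person_id", "survey_year", "stratum",
                                   "psu", "weight"))
}

#' Apply the survey exclusion rules
#'
#' Removes respondents under 2 years of age, pregnant respondents,
#' breast-milk-only children, and person-days without a valid recall, in
#' that order of precedence for the per-reason tally. Idempotent.
#'
#' @param records A recall tibble.
#' @return A list with `records` (retained rows) and `counts`, a named
#'   vector of removed-record counts per reason
#'   (`age<2`, `pregnant`, `breastmilk_only`, `invalid`).
#' @export
#' @examples
#' pop <- generate_population(generator_config(n_2004 = 200, n_2015 = 0))
#' apply_exclusions(pop$records)$counts
apply_exclusions <- function(records) {
  reason <- dplyr::case_when(
    records$age_years < 2 ~ "age<2",
    records$pregnant ~ "pregnant",
    records$breastmilk_only ~ "breastmilk_only",
    !records$valid_recall ~ "invalid",
    TRUE ~ NA_character_)
  counts <- table(factor(reason,
                         levels = c("age<2", "pregnant", "breastmilk_only",
                                    "invalid")))
  list(records = records[is.na(reason), , drop = FALSE],
       counts = setNames(as.integer(counts), names(counts)))
}

#' Write a cohort to CSV
#'
#' Serializes recall records and the survey design to the package's CSV
#' interchange formats: `recalls.csv` (one row per person-day) and
#' `weights.csv` (`person_id`, `weight`, `w_rep_001` ...). Output is
#' byte-stable for a fixed generator seed.
#'
#' @param population Output of [generate_population()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rp <- file.path(dir, "recalls.csv")
  wp <- file.path(dir, "weights.csv")
  readr::write_csv(population$records, rp)
  w <- population$design$rep_weights
  colnames(w) <- sprintf("w_rep_%03d", seq_len(ncol(w)))
  readr::write_csv(dplyr::bind_cols(population$design$persons,
                                    as_tibble(w)), wp)
  invisible(c(recalls = rp, weights = wp))
}
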