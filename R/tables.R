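#' Published reference tables for the 2004/2015 Canadian burden analyses
#'
#' The package ships transcriptions of the published Canadian estimates of
#' diet-quality distributions and attributable burden, used as anchors by
#' the validation suite and as ready-made inputs for stages downstream of
#' scoring:
#'
#' * `reference_quintile_proportions()` — survey-weighted percentage of the
#'   population in each diet-quality quintile by sex, cost age group, and
#'   survey year (2004, 2015).
#' * `reference_pafs()` — published population-attributable fractions (%) by
#'   sex, age group, disease and year, plus the 2015-2004 change.
#' * `reference_burden()` — published attributable direct, indirect and
#'   total costs (2017 CAD) by disease, age group and sex, with the
#'   2015-2004 change in totals. One cell of the source table drops a digit
#'   (the female 2015 direct column); the transcription restores it from the
#'   table's own column arithmetic.
#'
#' @param long For `reference_quintile_proportions()`, return the table in
#'   long year format (one row per year/sex/age/quintile) instead of the
#'   wide `P1..P5` layout used by the PAF stage.
#' @return A tibble; see Details.
#' @export
reference_quintile_proportions <- function(long = FALSE) {
  raw <- read_extdata("reference_quintile_proportions.csv")
  out <- raw %>%
    tidyr::pivot_longer(c("p_2004", "p_2015"), names_to = "year",
                        names_prefix = "p_", values_to = "pct") %>%
    mutate(year = as.integer(.data$year))
  if (long) return(out)
  out %>%
    mutate(quintile = paste0("P", .data$quintile), p = .data$pct / 100) %>%
    select(-"pct") %>%
    tidyr::pivot_wider(names_from = "quintile", values_from = "p") %>%
    select("year", "sex", "age_group", "P1", "P2", "P3", "P4", "P5")
}

#' @rdname reference_quintile_proportions
#' @export
reference_pafs <- function() {
  read_extdata("reference_pafs.csv") %>%
    tidyr::pivot_longer(-c("age_group", "disease", "icd10"),
                        names_to = c("sex", "measure"), names_sep = "_",
                        values_to = "value") %>%
    tidyr::pivot_wider(names_from = "measure", values_from = "value") %>%
    rename(paf_2004 = "2004", paf_2015 = "2015", paf_delta = "delta") %>%
    filter(!is.na(.data$paf_2004))
}

#' @rdname reference_quintile_proportions
#' @export
reference_burden <- function() {
  read_extdata("reference_burden.csv")
}

read_extdata <- function(file) {
  path <- system.file("extdata", file, package = "dietburden",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Default relative-risk table
#'
#' The quintile-5-versus-quintile-1 relative risks used by the published
#' analysis come from meta-analyses and are not reproduced here. The default
#' table is instead derived at run time: each disease's relative risk is
#' recovered by numerically inverting its published male <15 2004 PAF
#' against the male <15 2004 quintile proportions (see [invert_rr()]), so
#' the defaults are exactly consistent with the published PAF table under
#' the package's exposure model. The 95% CI is a synthetic +-15% band on the
#' log scale, flagged by `source = "synthetic_ci"`; supply a real table (CSV
#' with the same columns) for substantive work.
#'
#' @param ci_log_halfwidth Half-width of the synthetic log-scale CI band.
#' @param exponents Quintile exponents, see [quintile_rr()].
#' @return A tibble: `disease`, `icd10`, `rr`, `ci_low`, `ci_high`,
#'   `sex_applicability`, `source`.
#' @export
#' @examples
#' default_rr_table()[1:3, ]
default_rr_table <- function(ci_log_halfwidth = 0.15,
                             exponents = c(-3.5, -2.5, -1.5, -0.5)) {
  anchors <- read_extdata("reference_pafs.csv") %>%
    filter(.data$age_group == "<15")
  props <- reference_quintile_proportions() %>%
    filter(.data$year == 2004, .data$sex == "male",
           .data$age_group == "<15")
  p <- c(props$P1, props$P2, props$P3, props$P4)
  tibble(
    disease = anchors$disease, icd10 = anchors$icd10,
    rr = vapply(anchors$male_2004 / 100,
                function(t) invert_rr(p, t, exponents), numeric(1)),
    sex_applicability = ifelse(anchors$disease == "Prostate cancer",
                               "male_only", "both"),
    source = "synthetic_ci") %>%
    mutate(ci_low = .data$rr * exp(-ci_log_halfwidth),
           ci_high = .data$rr * exp(ci_log_halfwidth)) %>%
    select("disease", "icd10", "rr", "ci_low", "ci_high",
           "sex_applicability", "source")
}

#' @rdname default_rr_table
#' @param path Path to an RR CSV (`disease`, `icd10`, `rr`, `ci_low`,
#'   `ci_high`, `sex_applicability`, optional `rr_male`/`rr_female`
#'   overrides and `source`).
#' @export
read_rr_table <- function(path) {
  validate_rr_table(readr::read_csv(path, show_col_types = FALSE))
}

#' Synthetic cost tables
#'
#' Stand-ins for the restricted administrative cost inputs (disease cost
#' shares of national hospital/physician/drug expenditure by sex and age
#' group, national expenditure totals, and disease-level indirect:direct
#' cost ratios). All three are synthetic: deterministic, plausible in scale
#' and structure (costs concentrated in older age groups and in
#' cardiovascular disease and diabetes), and intended only to exercise the
#' costing pipeline. Expenditure totals are round 2017-order-of-magnitude
#' figures in 2017 CAD.
#'
#' @return A list of tibbles: `shares` (disease, sex, age_group, component,
#'   share), `totals` (component, total), `ratios` (disease, ratio).
#' @export
synthetic_cost_tables <- function() {
  diseases <- read_extdata("reference_pafs.csv") %>%
    distinct(.data$disease, .data$icd10)
  # relative prevalence-cost size of each disease, roughly echoing the
  # ordering of published burden tables
  size <- c("Colorectal cancer" = 0.5, "Esophagus cancer" = 0.15,
            "Stomach cancer" = 0.25, "Hepatocellular cancer" = 0.06,
            "Larynx cancer" = 0.1, "Oral cancer" = 0.35,
            "Pancreas cancer" = 0.5, "Prostate cancer" = 0.9,
            "Lung cancer" = 0.9, "Type 2 diabetes" = 6,
            "Ischemic stroke" = 2.1, "Heart failure" = 2.3,
            "Ischemic heart disease" = 9.5)
  age_gradient <- c("<15" = 0.02, "15-34" = 0.08, "35-54" = 0.45,
                    "55-64" = 0.9, "65-74" = 1.4, "75+" = 2.2)
  comp_split <- c(hospitals = 0.55, physicians = 0.2, drugs = 0.25)
  grid <- tidyr::expand_grid(diseases,
                             sex = c("male", "female"),
                             age_group = names(age_gradient),
                             component = names(comp_split))
  shares <- grid %>%
    mutate(share = 0.001 * size[.data$disease] *
             age_gradient[.data$age_group] *
             comp_split[.data$component] / 0.35 *
             ifelse(.data$sex == "male", 1.1, 0.9)) %>%
    mutate(share = ifelse(.data$disease == "Prostate cancer" &
                            .data$sex == "female", 0, .data$share))
  totals <- tibble(component = c("hospitals", "physicians", "drugs"),
                   total = c(66.7e9, 37.4e9, 33.7e9))
  ratios <- diseases %>%
    mutate(ratio = c(4.9, 4.9, 4.9, 4.9, 4.9, 4.9, 4.9, 4.9, 4.9,
                     1.21, 1.72, 1.72, 1.72)[
                       match(.data$disease, names(size))])
  list(shares = shares, totals = totals, ratios = ratios)
}
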