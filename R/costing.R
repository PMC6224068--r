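#' Direct and indirect disease costs
#'
#' `direct_costs()` turns disease shares of national expenditure into 2017
#' dollars: for every (disease, sex, age group) cell the direct cost is the
#' sum over expenditure components (hospitals, physicians, drugs) of
#' `share x component total`. Diabetes cost shares cover all diabetes types
#' combined, so diabetes cells are multiplied by 0.96 to isolate type 2;
#' because this happens at the direct-cost step, indirect costs inherit it.
#'
#' `indirect_costs()` multiplies each cell's direct cost by the disease-level
#' indirect:direct ratio (a human-capital valuation of mortality and
#' disability losses); ratios are disease-level only, so the indirect:direct
#' quotient is constant across a disease's age/sex cells by construction.
#'
#' @param shares Tibble `disease`, `sex`, `age_group`, `component`, `share`
#'   (fractions of national component expenditure).
#' @param totals Tibble `component`, `total` (2017 CAD).
#' @param diabetes_fraction Fraction of combined-diabetes costs assigned to
#'   type 2 (default 0.96).
#' @return `direct_costs()`: tibble `disease`, `sex`, `age_group`, `direct`.
#'   `indirect_costs()`: the same cells with `indirect` added.
#' @export
direct_costs <- function(shares, totals, diabetes_fraction = 0.96) {
  need <- c("disease", "sex", "age_group", "component", "share")
  if (length(setdiff(need, names(shares)))) {
    abort("shares table needs columns disease, sex, age_group, component, share")
  }
  miss <- setdiff(unique(shares$component), totals$component)
  if (length(miss)) {
    abort(paste0("expenditure totals missing component(s): ",
                 paste(miss, collapse = ", ")))
  }
  shares %>%
    inner_join(totals, by = "component") %>%
    group_by(.data$disease, .data$sex, .data$age_group) %>%
    summarise(direct = sum(.data$share * .data$total), .groups = "drop") %>%
    mutate(direct = .data$direct *
             ifelse(.data$disease == "Type 2 diabetes",
                    diabetes_fraction, 1))
}

#' @rdname direct_costs
#' @param direct Output of `direct_costs()`.
#' @param ratios Tibble `disease`, `ratio` (indirect:direct).
#' @export
indirect_costs <- function(direct, ratios) {
  miss <- setdiff(unique(direct$disease), ratios$disease)
  if (length(miss)) {
    abort(paste0("indirect-ratio table missing disease(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(ratios$ratio < 0)) abort("indirect ratios must be nonnegative")
  direct %>%
    inner_join(ratios %>% select("disease", "ratio"), by = "disease") %>%
    mutate(indirect = .data$direct * .data$ratio) %>%
    select(-"ratio")
}

#' Attributable burden by disease, sex, age group and year
#'
#' Multiplies each stratum's direct and indirect cost by its PAF to obtain
#' the burden attributable to unhealthy eating, for every survey year in the
#' PAF table. Strata must align: any (disease, sex, age group) present in
#' the PAF table but absent from the cost table (or vice versa, prostate
#' cancer in females excepted) is an error.
#'
#' @param pafs A PAF table (see [paf_table()]): `year`, `sex`, `age_group`,
#'   `disease`, `paf` as fractions.
#' @param costs Output of [indirect_costs()].
#' @param drop_children Drop the `<15` age stratum (robustness variant).
#' @param drop_stomach Drop stomach cancer (robustness variant).
#' @return A `burden_cells` tibble: `year`, `disease`, `sex`, `age_group`,
#'   `direct`, `indirect`, `total` (2017 CAD, full precision).
#' @export
attributable_burden <- function(pafs, costs, drop_children = FALSE,
                                drop_stomach = FALSE) {
  if (drop_children) {
    pafs <- filter(pafs, .data$age_group != "<15")
    costs <- filter(costs, .data$age_group != "<15")
  }
  if (drop_stomach) {
    pafs <- filter(pafs, .data$disease != "Stomach cancer")
    costs <- filter(costs, .data$disease != "Stomach cancer")
  }
  costs <- filter(costs,
                  !(.data$disease == "Prostate cancer" &
                      .data$sex == "female"))
  keys <- c("disease", "sex", "age_group")
  # every stratum must be present for every survey year in the PAF table
  grid <- tidyr::expand_grid(year = unique(pafs$year),
                             distinct(pafs, across(all_of(keys))))
  unmatched <- bind_rows(
    anti_join(grid, pafs, by = c("year", keys)) %>% select(-"year"),
    anti_join(distinct(pafs, across(all_of(keys))), costs, by = keys),
    anti_join(costs %>% distinct(across(all_of(keys))),
              pafs, by = keys))
  if (nrow(unmatched)) {
    abort(paste0("PAF and cost strata do not align; unmatched: ",
                 paste(utils::capture.output(print(as.data.frame(
                   utils::head(unmatched, 5)))), collapse = " | ")))
  }
  pafs %>%
    inner_join(costs, by = keys) %>%
    mutate(direct = .data$paf * .data$direct,
           indirect = .data$paf * .data$indirect,
           total = .data$direct + .data$indirect) %>%
    select("year", "disease", "sex", "age_group", "direct", "indirect",
           "total") %>%
    arrange(.data$year, .data$disease, .data$sex,
            match(.data$age_group, cost_age_levels()))
}

#' Marginal totals of a burden table
#'
#' Aggregates burden cells into the marginal layout of a published
#' burden-of-disease table: per-disease, per-age-group and per-sex totals
#' plus the grand total, per year.
#'
#' @param cells Output of [attributable_burden()] (or any tibble with
#'   `year`, `disease`, `sex`, `age_group`, `direct`, `indirect`, `total`).
#' @return A tibble with `section` (`disease`/`age`/`sex`/`total`), `key`,
#'   `year`, `direct`, `indirect`, `total`.
#' @export
burden_marginals <- function(cells) {
  agg <- function(section, key_col) {
    cells %>%
      group_by(year = .data$year,
               key = if (is.null(key_col)) "total" else
                 .data[[key_col]]) %>%
      summarise(direct = sum(.data$direct), indirect = sum(.data$indirect),
                total = sum(.data$total), .groups = "drop") %>%
      mutate(section = section, .before = 1)
  }
  bind_rows(agg("disease", "disease"),
            agg("age", "age_group"),
            agg("sex", "sex"),
            agg("total", NULL))
}

#' Year-on-year burden differences
#'
#' Cellwise later-minus-earlier differences of attributable costs on
#' identical (disease, sex, age group) strata.
#'
#' @param cells_late,cells_early Burden cell tables for the two years
#'   ([attributable_burden()] output filtered to one year each, or a
#'   two-year table split by `year`).
#' @return The strata with `d_direct`, `d_indirect`, `d_total`.
#' @export
burden_delta <- function(cells_late, cells_early) {
  keys <- c("disease", "sex", "age_group")
  a <- cells_late %>% select(all_of(keys), "direct", "indirect", "total")
  b <- cells_early %>% select(all_of(keys), "direct", "indirect", "total")
  if (nrow(a) != nrow(b) ||
      nrow(anti_join(a[keys], b[keys], by = keys)) > 0) {
    abort("mismatched strata between burden tables")
  }
  inner_join(a, b, by = keys, suffix = c("_late", "_early")) %>%
    mutate(d_direct = .data$direct_late - .data$direct_early,
           d_indirect = .data$indirect_late - .data$indirect_early,
           d_total = .data$total_late - .data$total_early) %>%
    select(all_of(keys), "d_direct", "d_indirect", "d_total")
}

#' Sensitivity bounds from the relative-risk confidence intervals
#'
#' Re-runs the PAF and burden stages twice, once with every disease's
#' relative risk set to the 95% bound nearer the null (rr = 1) and once to
#' the bound farther from it, yielding two complete burden tables that
#' bracket the central one: a relative risk closer to 1 gives a smaller PAF,
#' hence a smaller burden, so for the protective risks typical here
#' (rr < 1) the `low` report uses `ci_high` and the `high` report `ci_low`.
#' PAFs are plug-in evaluations here (the bounds are deterministic
#' scenarios, not draws).
#'
#' @param proportions Quintile proportion table (see [paf_table()]).
#' @param rr_table Relative-risk table with `ci_low`/`ci_high`.
#' @param costs Output of [indirect_costs()].
#' @param exponents Quintile exponents.
#' @param ... Passed to [attributable_burden()].
#' @return A list of two burden-cell tables, `low` and `high`.
#' @export
sensitivity_bounds <- function(proportions, rr_table, costs,
                               exponents = c(-3.5, -2.5, -1.5, -0.5), ...) {
  run_at <- function(bound) {
    rt <- rr_table %>%
      mutate(rr = bound) %>%
      mutate(ci_low = .data$rr, ci_high = .data$rr)
    pafs <- plugin_paf_table(proportions, rt, exponents)
    attributable_burden(pafs, costs, ...)
  }
  # the bound nearer the null rr = 1 yields the smaller PAF and burden
  near <- ifelse(rr_table$rr <= 1, rr_table$ci_high, rr_table$ci_low)
  far <- ifelse(rr_table$rr <= 1, rr_table$ci_low, rr_table$ci_high)
  list(low = run_at(near), high = run_at(far))
}

# deterministic plug-in PAF table (no Monte Carlo); used by the
# sensitivity bounds and wherever the point pipeline suffices
plugin_paf_table <- function(proportions, rr_table,
                             exponents = c(-3.5, -2.5, -1.5, -0.5)) {
  validate_rr_table(rr_table)
  props <- proportions %>%
    tidyr::expand_grid(rr_table %>%
                         select("disease", "icd10", "rr",
                                "sex_applicability")) %>%
    filter(!(.data$sex_applicability == "male_only" &
               .data$sex != "male"))
  props$paf <- vapply(seq_len(nrow(props)), function(i) {
    paf_point(c(props$P1[i], props$P2[i], props$P3[i], props$P4[i]),
              props$rr[i], exponents)
  }, numeric(1))
  props %>% select("year", "sex", "age_group", "disease", "icd10", "paf")
}
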