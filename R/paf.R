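#' Population-attributable fractions across quintile exposure levels
#'
#' The PAF machinery treats quintile 5 of the diet-quality score as the
#' reference exposure and assumes a log-linear dose-response across
#' quintiles. Given the meta-analytic relative risk `rr` comparing quintile
#' 5 with quintile 1 (typically < 1), the risk of quintile `i` relative to
#' quintile 5 is
#'
#'   RR_i = rr ^ e_i,
#'
#' where the exponent `e_i` is the quintile's mid-index minus the lower cut
#' of quintile 5 on the quintile-index scale: `e = (-3.5, -2.5, -1.5, -0.5)`
#' by default (quintile mid-values 0.5, 1.5, 2.5, 3.5 against the cut at 4).
#' The PAF over the four non-reference quintiles with population shares
#' `P1..P4` is
#'
#'   PAF = S / (1 + S),  S = sum_i P_i (RR_i - 1).
#'
#' `quintile_rr()` returns RR_1..RR_4; `paf_point()` the plug-in PAF;
#' `invert_rr()` numerically recovers the `rr` that yields a target PAF for
#' given proportions (unique, since the PAF is strictly decreasing in `rr`
#' on (0, 1]); `paf_mc()` propagates the relative risk's 95% CI through the
#' PAF by Monte-Carlo sampling of a lognormal `rr`.
#'
#' @param rr Quintile-5-versus-quintile-1 relative risk, > 0.
#' @param exponents Exponents `e_1..e_4`; strictly increasing and negative.
#' @param p Proportions `P1..P4` of the four quintiles below quintile 5
#'   (fractions; a length-5 vector is accepted and its first four entries
#'   used).
#' @return `quintile_rr()`: the four relative risks versus quintile 5.
#'   `paf_point()`: the PAF as a fraction. `invert_rr()`: the relative risk.
#'   `paf_mc()`: a list with `paf` (Monte-Carlo mean), `ci_low`, `ci_high`
#'   (2.5/97.5 percentiles), `paf_plugin`, `n_draws`, `seed`.
#' @export
#' @examples
#' quintile_rr(0.77)
#' p <- c(0.188, 0.186, 0.203, 0.219)
#' rr <- invert_rr(p, 0.367)
#' paf_point(c(0.157, 0.200, 0.205, 0.252), rr)  # ~0.356
quintile_rr <- function(rr, exponents = c(-3.5, -2.5, -1.5, -0.5)) {
  if (any(rr <= 0)) abort("rr must be > 0")
  rr^exponents
}

#' @rdname quintile_rr
#' @export
paf_point <- function(p, rr, exponents = c(-3.5, -2.5, -1.5, -0.5)) {
  p <- check_proportions(p)
  s <- sum(p * (quintile_rr(rr, exponents) - 1))
  s / (1 + s)
}

#' @rdname quintile_rr
#' @param paf_target Target PAF in `[0, 1)`.
#' @param interval Search bracket for `rr`.
#' @export
invert_rr <- function(p, paf_target, exponents = c(-3.5, -2.5, -1.5, -0.5),
                      interval = c(1e-6, 1)) {
  p <- check_proportions(p)
  if (paf_target < 0 || paf_target >= 1) {
    abort("paf_target must be in [0, 1)")
  }
  if (paf_target == 0) return(1)
  f <- function(rr) paf_point(p, rr, exponents) - paf_target
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi)) {
    abort("paf_target is not attainable within the rr bracket")
  }
  uniroot(f, interval, tol = 1e-12)$root
}

#' @rdname quintile_rr
#' @param ci_low,ci_high 95% CI bounds of `rr`.
#' @param n_draws Monte-Carlo draws (default 50000).
#' @param seed Integer seed recorded in the result.
#' @export
paf_mc <- function(p, rr, ci_low, ci_high, n_draws = 50000,
                   exponents = c(-3.5, -2.5, -1.5, -0.5), seed = 1L) {
  p <- check_proportions(p)
  if (!(ci_low <= rr && rr <= ci_high) || ci_low <= 0) {
    abort("require 0 < ci_low <= rr <= ci_high")
  }
  sigma <- (log(ci_high) - log(ci_low)) / (2 * 1.96)
  plugin <- paf_point(p, rr, exponents)
  if (sigma == 0) {
    return(list(paf = plugin, ci_low = plugin, ci_high = plugin,
                paf_plugin = plugin, n_draws = as.integer(n_draws),
                seed = as.integer(seed)))
  }
  set.seed(seed)
  draws <- rlnorm(n_draws, log(rr), sigma)
  rrq <- outer(draws, exponents, `^`)              # n_draws x 4
  s <- drop(rrq %*% p) - sum(p)
  pafs <- s / (1 + s)
  qs <- unname(quantile(pafs, c(0.025, 0.975), type = 1))
  list(paf = mean(pafs), ci_low = qs[1], ci_high = qs[2],
       paf_plugin = plugin, n_draws = as.integer(n_draws),
       seed = as.integer(seed))
}

check_proportions <- function(p) {
  if (length(p) == 5) p <- p[1:4]
  if (length(p) != 4) abort("expected proportions P1..P4 (or P1..P5)")
  if (any(p < 0) || sum(p) > 1 + 1e-9) {
    abort("proportions must be nonnegative with sum(P1..P4) <= 1")
  }
  p
}

#' PAF estimates for every stratum and disease
#'
#' Crosses a quintile-proportion table (one row per year, sex, cost age
#' group; see [tabulate_proportions()]) with a relative-risk table (one row
#' per disease) and computes the Monte-Carlo PAF for every combination.
#' Male-only diseases (prostate cancer) are skipped for females. Per-sex
#' relative-risk overrides are honoured when the RR table carries
#' `rr_male`/`rr_female` columns.
#'
#' @param proportions Tibble with `year`, `sex`, `age_group`, `P1..P4`.
#' @param rr_table Tibble with `disease`, `icd10`, `rr`, `ci_low`,
#'   `ci_high`, `sex_applicability` (`"both"` or `"male_only"`).
#' @param n_draws,exponents,seed Passed to [paf_mc()].
#' @return A tibble with one row per (year, sex, age_group, disease):
#'   `paf`, `ci_low`, `ci_high`, `paf_plugin`, `n_draws`, `seed`.
#' @export
paf_table <- function(proportions, rr_table, n_draws = 50000,
                      exponents = c(-3.5, -2.5, -1.5, -0.5), seed = 1L) {
  validate_rr_table(rr_table)
  rows <- list()
  for (i in seq_len(nrow(proportions))) {
    pr <- proportions[i, ]
    p <- c(pr$P1, pr$P2, pr$P3, pr$P4)
    for (j in seq_len(nrow(rr_table))) {
      rr_row <- rr_table[j, ]
      if (rr_row$sex_applicability == "male_only" && pr$sex != "male") next
      rr <- rr_row$rr
      scale <- 1
      override <- paste0("rr_", pr$sex)
      if (override %in% names(rr_table) && !is.na(rr_row[[override]])) {
        scale <- rr_row[[override]] / rr
        rr <- rr_row[[override]]
      }
      est <- paf_mc(p, rr, rr_row$ci_low * scale, rr_row$ci_high * scale,
                    n_draws = n_draws, exponents = exponents,
                    seed = seed + 7L * i + j)
      rows[[length(rows) + 1L]] <- tibble(
        year = pr$year, sex = pr$sex, age_group = pr$age_group,
        disease = rr_row$disease, icd10 = rr_row$icd10,
        paf = est$paf, ci_low = est$ci_low, ci_high = est$ci_high,
        paf_plugin = est$paf_plugin, n_draws = est$n_draws,
        seed = est$seed)
    }
  }
  bind_rows(rows)
}

#' Year-on-year PAF differences
#'
#' Elementwise later-minus-earlier PAF difference on identical
#' (sex, age group, disease) strata.
#'
#' @param paf_late,paf_early PAF tables for the two years (see
#'   [paf_table()]); strata must match exactly.
#' @return The `paf_late` strata with `paf_delta = paf_late - paf_early`.
#' @export
paf_delta <- function(paf_late, paf_early) {
  keys <- c("sex", "age_group", "disease")
  a <- paf_late %>% select(all_of(keys), paf_late = "paf")
  b <- paf_early %>% select(all_of(keys), paf_early = "paf")
  if (nrow(a) != nrow(b) || nrow(anti_join(a, b, by = keys)) > 0 ||
      nrow(anti_join(b, a, by = keys)) > 0) {
    abort("mismatched strata between the two PAF tables")
  }
  inner_join(a, b, by = keys) %>%
    mutate(paf_delta = .data$paf_late - .data$paf_early)
}

validate_rr_table <- function(rr_table) {
  need <- c("disease", "icd10", "rr", "ci_low", "ci_high",
            "sex_applicability")
  missing <- setdiff(need, names(rr_table))
  if (length(missing)) {
    abort(paste0("rr table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  with(rr_table, {
    if (any(!(ci_low > 0 & ci_low <= rr & rr <= ci_high))) {
      abort("rr table must satisfy 0 < ci_low <= rr <= ci_high")
    }
  })
  invisible(rr_table)
}
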