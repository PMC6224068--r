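#' Pipeline configuration
#'
#' Collects every knob of the end-to-end pipeline with defaults matching the
#' package's documented design choices. The configuration round-trips
#' losslessly through [jsonlite::toJSON()]/[jsonlite::fromJSON()] and its
#' hash is recorded in the run manifest, so two runs with the same config
#' and seed are identical.
#'
#' @param generator A [generator_config()] used when no recall data is
#'   supplied.
#' @param proportions_csv Optional path to a quintile-proportion CSV
#'   (columns `year`, `sex`, `age_group`, `P1..P5`); when set, the
#'   simulate/score/distribution stages are skipped and the pipeline starts
#'   at the PAF stage.
#' @param rr_table Relative-risk table (tibble or CSV path); default
#'   [default_rr_table()].
#' @param cost_tables List of `shares`, `totals`, `ratios` (see
#'   [synthetic_cost_tables()]).
#' @param n_draws Monte-Carlo draws per PAF (default 50000).
#' @param exponents Quintile exponents.
#' @param pooling Quintile cutpoint pooling policy: `"pooled_years"`
#'   (default), `"per_year"`, or `"reference_year"` (cutpoints from the
#'   earlier year).
#' @param basis Serving-standard basis, see [score_cohort()].
#' @param drop_children,drop_stomach Robustness toggles, see
#'   [attributable_burden()].
#' @param seed Integer seed for every random stage.
#' @param out_dir Output directory for CSV artifacts; `NULL` writes nothing.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       proportions_csv = NULL,
                       rr_table = NULL,
                       cost_tables = NULL,
                       n_draws = 50000,
                       exponents = c(-3.5, -2.5, -1.5, -0.5),
                       pooling = c("pooled_years", "per_year",
                                   "reference_year"),
                       basis = c("absolute", "per_1000_kcal"),
                       drop_children = FALSE, drop_stomach = FALSE,
                       seed = 1L, out_dir = NULL) {
  cfg <- list(generator = generator, proportions_csv = proportions_csv,
              rr_table = rr_table, cost_tables = cost_tables,
              n_draws = as.integer(n_draws), exponents = exponents,
              pooling = match.arg(pooling), basis = match.arg(basis),
              drop_children = drop_children, drop_stomach = drop_stomach,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full burden-estimation pipeline
#'
#' Executes the four analysis steps in order — (1) estimate the quintile
#' distribution of diet quality (simulate a cohort, apply exclusions, score
#' with the HEI-C 2010, tabulate weighted quintile proportions with BRR
#' standard errors), (2) load relative risks, (3) compute Monte-Carlo PAFs
#' per year/sex/age/disease, (4) attribute direct and indirect 2017-dollar
#' costs and difference the years — plus the RR-CI sensitivity bounds. A
#' stage failure aborts with the stage name. When `out_dir` is set, writes
#' `scores.csv`, `proportions.csv`, `paf.csv`, `burden.csv`,
#' `burden_delta.csv` and `manifest.json` (seed, config hash, versions,
#' record counts and exclusion tallies).
#'
#' @param config A [run_config()].
#' @return A list: `proportions`, `pafs`, `burden` (cells), `marginals`,
#'   `delta`, `sensitivity` (`low`/`high` cell tables), `manifest`, and —
#'   when scoring ran — `scores` and `exclusions`.
#' @export
#' @examples
#' \donttest{
#' cfg <- run_config(generator = generator_config(n_2004 = 300,
#'                                                n_2015 = 300, seed = 7),
#'                   n_draws = 200, seed = 7)
#' res <- run_pipeline(cfg)
#' res$marginals[res$marginals$section == "total", ]
#' }
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  out <- list()
  manifest <- list(seed = config$seed,
                   config_hash = rlang::hash(unclass(config)),
                   package_version =
                     as.character(utils::packageVersion("dietburden")),
                   r_version = as.character(getRversion()))

  if (is.null(config$proportions_csv)) {
    pop <- stage("simulate", {
      gen <- config$generator
      gen$seed <- config$seed
      generate_population(gen)
    })
    excl <- stage("exclusions", apply_exclusions(pop$records))
    manifest$n_records <- nrow(pop$records)
    manifest$n_retained <- nrow(excl$records)
    manifest$exclusions <- as.list(excl$counts)
    scores <- stage("score", {
      intake <- aggregate_person_intake(excl$records)
      intake <- filter(intake, .data$energy_kcal > 0)
      sc <- score_cohort(intake, basis = config$basis)
      sc$sex <- intake$sex
      sc$age_group <- cost_age_group(intake$age_years)
      sc
    })
    proportions <- stage("distribution", {
      quintile_distribution(
        tibble(person_id = scores$person_id,
               survey_year = scores$survey_year, sex = scores$sex,
               age_group = scores$age_group, total = scores$total),
        pop$design, pooling = config$pooling)
    })
    out$scores <- scores
    out$exclusions <- excl$counts
  } else {
    proportions <- stage("distribution", {
      readr::read_csv(config$proportions_csv, show_col_types = FALSE)
    })
  }

  rr <- stage("paf", {
    if (is.null(config$rr_table)) default_rr_table(exponents =
                                                     config$exponents)
    else if (is.character(config$rr_table)) read_rr_table(config$rr_table)
    else validate_rr_table(config$rr_table)
  })
  pafs <- stage("paf", paf_table(proportions, rr,
                                 n_draws = config$n_draws,
                                 exponents = config$exponents,
                                 seed = config$seed))
  costs <- stage("burden", {
    ct <- if (is.null(config$cost_tables)) synthetic_cost_tables()
          else config$cost_tables
    indirect_costs(direct_costs(ct$shares, ct$totals), ct$ratios)
  })
  burden <- stage("burden", attributable_burden(
    pafs, costs, drop_children = config$drop_children,
    drop_stomach = config$drop_stomach))
  years <- sort(unique(burden$year))
  delta <- if (length(years) == 2) {
    stage("burden", burden_delta(filter(burden, .data$year == years[2]),
                                 filter(burden, .data$year == years[1])))
  } else NULL
  sens <- stage("sensitivity", sensitivity_bounds(
    proportions, rr, costs, exponents = config$exponents,
    drop_children = config$drop_children,
    drop_stomach = config$drop_stomach))

  out <- c(out, list(proportions = proportions, pafs = pafs,
                     burden = burden,
                     marginals = burden_marginals(burden), delta = delta,
                     sensitivity = sens, manifest = manifest))
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(out$scores)) {
    readr::write_csv(out$scores, file.path(dir, "scores.csv"))
  }
  readr::write_csv(out$proportions, file.path(dir, "proportions.csv"))
  readr::write_csv(out$pafs, file.path(dir, "paf.csv"))
  readr::write_csv(out$burden, file.path(dir, "burden.csv"))
  if (!is.null(out$delta)) {
    readr::write_csv(out$delta, file.path(dir, "burden_delta.csv"))
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Regenerate the validation fixture bundle
#'
#' Writes the transcribed reference tables (quintile proportions, PAF
#' anchors, burden table) and a small synthetic cohort to a directory.
#' Idempotent for a fixed seed.
#'
#' @param dir Output directory.
#' @param seed Seed for the synthetic cohort.
#' @return Invisibly, the directory.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(reference_quintile_proportions(),
                   file.path(dir, "reference_quintile_proportions.csv"))
  readr::write_csv(reference_pafs(), file.path(dir, "reference_pafs.csv"))
  readr::write_csv(reference_burden(),
                   file.path(dir, "reference_burden.csv"))
  pop <- generate_population(
    generator_config(n_2004 = 250, n_2015 = 250, seed = seed))
  write_cohort(pop, dir)
  invisible(dir)
}

#' Human-readable burden summary
#'
#' Prints year totals, sex and age marginals, year-on-year deltas, and the
#' top diseases by attributable burden.
#'
#' @param result A [run_pipeline()] result (or a list with `burden`).
#' @param top Number of top diseases to show.
#' @return Invisibly, the marginal table.
#' @export
report_summary <- function(result, top = 5) {
  cells <- result$burden
  marg <- burden_marginals(cells)
  fmt <- function(x) formatC(x, format = "f", digits = 0, big.mark = " ")
  for (yr in sort(unique(marg$year))) {
    tot <- filter(marg, .data$section == "total", .data$year == yr)
    cat(sprintf("Year %s: direct %s, indirect %s, total %s CAD\n", yr,
                fmt(tot$direct), fmt(tot$indirect), fmt(tot$total)))
  }
  for (sec in c("sex", "age")) {
    sub <- filter(marg, .data$section == sec)
    for (k in unique(sub$key)) {
      rows <- filter(sub, .data$key == k)
      cat(sprintf("  %s %-6s total by year: %s\n", sec, k,
                  paste(fmt(rows$total), collapse = " / ")))
    }
  }
  years <- sort(unique(cells$year))
  if (length(years) == 2) {
    d <- burden_delta(filter(cells, .data$year == years[2]),
                      filter(cells, .data$year == years[1]))
    cat(sprintf("Change %s vs %s: total %s CAD\n", years[2], years[1],
                fmt(sum(d$d_total))))
  }
  top_d <- marg %>%
    filter(.data$section == "disease") %>%
    group_by(.data$key) %>%
    summarise(total = sum(.data$total), .groups = "drop") %>%
    arrange(dplyr::desc(.data$total)) %>%
    head(top)
  cat("Top diseases by attributable burden (all years):\n")
  for (i in seq_len(nrow(top_d))) {
    cat(sprintf("  %-24s %s\n", top_d$key[i], fmt(top_d$total[i])))
  }
  invisible(marg)
}
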