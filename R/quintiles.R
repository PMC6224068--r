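#' Weighted quantiles and quintile assignment
#'
#' `weighted_quantiles()` computes weighted empirical quantiles as the
#' left-continuous inverse of the weighted ECDF (the weighted analogue of
#' type-1 quantiles): the cutpoint at probability `p` is the smallest
#' observed score whose cumulative weight share reaches `p`. This rule is
#' pinned for reproducibility. `assign_quintile()` bins scores into
#' right-closed intervals `(-Inf, c1], (c1, c2], ..., (c4, Inf)`; boundary
#' ties go to the lower quintile, and quintile 5 is the high-quality diet.
#'
#' By default cutpoints are computed on the pooled distribution of both
#' survey years, so the per-year quintile shares are free to drift from 20%
#' (a per-year policy would pin them at 20% and hide any temporal change).
#'
#' @param scores Numeric scores.
#' @param weights Positive weights (default equal).
#' @param probs Probabilities for the cutpoints.
#' @return `weighted_quantiles()`: a numeric vector of strictly increasing
#'   cutpoints. `assign_quintile()`: integer quintiles 1..5.
#' @export
#' @examples
#' weighted_quantiles(1:100)
#' assign_quintile(c(10, 30, 50, 70, 90), weighted_quantiles(1:100))
weighted_quantiles <- function(scores, weights = rep(1, length(scores)),
                               probs = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(length(scores) == length(weights))
  if (any(weights <= 0)) abort("weights must be strictly positive")
  o <- order(scores)
  s <- scores[o]
  cw <- cumsum(weights[o]) / sum(weights)
  cut <- vapply(probs, function(p) s[which(cw >= p - 1e-12)[1]], numeric(1))
  if (any(diff(cut) <= 0)) {
    abort("degenerate quintiles: cutpoints are not strictly increasing")
  }
  cut
}

#' @rdname weighted_quantiles
#' @param cutpoints Output of `weighted_quantiles()`.
#' @export
assign_quintile <- function(scores, cutpoints) {
  stopifnot(length(cutpoints) == 4, !is.unsorted(cutpoints, strictly = TRUE))
  findInterval(scores, cutpoints, left.open = TRUE) + 1L
}

#' Estimate the quintile distribution of diet quality with full BRR variance
#'
#' The one-stop estimator for the distribution stage: computes weighted
#' quintile cutpoints under the chosen pooling policy, assigns quintiles,
#' and estimates weighted quintile shares per (year, sex, cost age group)
#' cell with balanced-repeated-replication standard errors. Unlike
#' [tabulate_proportions()] applied to fixed quintile assignments, the
#' cutpoints are re-estimated inside every replicate, so the standard
#' errors carry the cutpoint-estimation uncertainty as well as the
#' share-estimation uncertainty.
#'
#' @param scores A tibble with one row per scored person: `person_id`,
#'   `survey_year`, `sex`, `age_group`, and the total score in `total`.
#' @param design A `survey_design` covering the same persons.
#' @param pooling `"pooled_years"` (cutpoints from both years combined, the
#'   default), `"per_year"`, or `"reference_year"` (cutpoints from the
#'   earliest year).
#' @return As [tabulate_proportions()], plus an attribute `cutpoints`.
#' @export
quintile_distribution <- function(scores, design,
                                  pooling = c("pooled_years", "per_year",
                                              "reference_year")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(design, "survey_design"))
  idx <- match(scores$person_id, design$persons$person_id)
  if (anyNA(idx)) abort("design does not cover all persons")
  w <- design$persons$weight[idx]
  wr <- design$rep_weights[idx, , drop = FALSE]
  R <- ncol(wr)
  n <- nrow(scores)

  pools <- switch(pooling,
    pooled_years = list(all = rep(TRUE, n)),
    reference_year = list(all = scores$survey_year ==
                            min(scores$survey_year)),
    per_year = {
      yrs <- sort(unique(scores$survey_year))
      setNames(lapply(yrs, function(y) scores$survey_year == y), yrs)
    })
  # full-sample assignment; for per_year each year uses its own cutpoints
  quintile <- integer(n)
  cuts_full <- list()
  assign_pool <- function(members, wts) {
    cp <- weighted_quantiles(scores$total[members], wts[members])
    list(cp = cp, q = assign_quintile(scores$total, cp))
  }
  for (nm in names(pools)) {
    members <- pools[[nm]]
    res <- assign_pool(members, w)
    cuts_full[[nm]] <- res$cp
    target <- if (pooling == "per_year") pools[[nm]] else rep(TRUE, n)
    quintile[target] <- res$q[target]
  }

  cells <- scores %>%
    distinct(.data$survey_year, .data$sex, .data$age_group) %>%
    arrange(.data$survey_year, .data$sex,
            match(.data$age_group, cost_age_levels()))
  cell_id <- match(paste(scores$survey_year, scores$sex, scores$age_group),
                   paste(cells$survey_year, cells$sex, cells$age_group))
  ncell <- nrow(cells)

  share_matrix <- function(wts, q) {
    num <- matrix(0, 5, ncell)
    s <- rowsum(wts, group = (cell_id - 1L) * 5L + q)
    pos <- as.integer(rownames(s))
    num[pos] <- s
    den <- rep(0, ncell)
    d <- rowsum(wts, group = cell_id)
    den[as.integer(rownames(d))] <- d
    sweep(num, 2, den, "/")
  }
  p_full <- share_matrix(w, quintile)

  # replicate loop: re-derive cutpoints and shares from replicate weights
  rep_shares <- array(NA_real_, c(5, ncell, R))
  for (r in seq_len(R)) {
    wtr <- wr[, r]
    qr <- integer(n)
    ok <- TRUE
    for (nm in names(pools)) {
      members <- pools[[nm]] & wtr > 0
      cp <- tryCatch(weighted_quantiles(scores$total[members],
                                        wtr[members]),
                     error = function(e) NULL)
      if (is.null(cp)) { ok <- FALSE; break }
      target <- if (pooling == "per_year") pools[[nm]] else rep(TRUE, n)
      qr[target] <- assign_quintile(scores$total, cp)[target]
    }
    if (ok) rep_shares[, , r] <- share_matrix(wtr, qr)
  }

  out <- lapply(seq_len(ncell), function(i) {
    se <- vapply(1:5, function(k) {
      reps <- rep_shares[k, i, ]
      reps <- reps[is.finite(reps)]
      if (!length(reps)) return(NA_real_)
      brr_se(reps, p_full[k, i], design$fay_rho)
    }, numeric(1))
    nc <- sum(cell_id == i)
    tibble(year = cells$survey_year[i], sex = cells$sex[i],
           age_group = cells$age_group[i], n = nc,
           !!!setNames(as.list(c(p_full[, i], se)),
                       c(paste0("P", 1:5), paste0("SE", 1:5))))
  })
  res <- bind_rows(out)
  attr(res, "cutpoints") <- cuts_full
  res
}

#' Survey-weighted quintile proportions with BRR standard errors
#'
#' Estimates the weighted share of each diet-quality quintile within every
#' (year, sex, cost age group) cell, with a balanced-repeated-replication
#' standard error per share. Empty cells are returned with missing
#' proportions and flagged, never silently zeroed.
#'
#' @param persons A tibble with one row per scored person: `person_id`,
#'   `survey_year`, `sex`, `age_group` (cost age group) and `quintile`.
#' @param design A `survey_design` from [brr_replicate_weights()] (or
#'   [generate_population()]) covering the same persons.
#' @param strata Optional tibble of expected cells (`survey_year`, `sex`,
#'   `age_group`); cells listed here but containing no persons are returned
#'   with `n = 0` and missing proportions rather than silently dropped.
#'   Default: the cells observed in `persons`.
#' @return A tibble with `year`, `sex`, `age_group`, `n`, and columns
#'   `P1..P5` (shares summing to 1 per cell) and `SE1..SE5`.
#' @export
tabulate_proportions <- function(persons, design, strata = NULL) {
  stopifnot(inherits(design, "survey_design"))
  idx <- match(persons$person_id, design$persons$person_id)
  if (anyNA(idx)) abort("design does not cover all persons")
  w <- design$persons$weight[idx]
  wr <- design$rep_weights[idx, , drop = FALSE]

  cells <- if (is.null(strata)) {
    distinct(persons, .data$survey_year, .data$sex, .data$age_group)
  } else {
    distinct(strata, .data$survey_year, .data$sex, .data$age_group)
  }
  cells <- cells %>%
    arrange(.data$survey_year, .data$sex,
            match(.data$age_group, cost_age_levels()))
  out <- lapply(seq_len(nrow(cells)), function(i) {
    in_cell <- persons$survey_year == cells$survey_year[i] &
      persons$sex == cells$sex[i] & persons$age_group == cells$age_group[i]
    q <- persons$quintile[in_cell]
    if (!length(q)) {
      return(tibble(year = cells$survey_year[i], sex = cells$sex[i],
                    age_group = cells$age_group[i], n = 0L,
                    !!!setNames(rep(list(NA_real_), 10),
                                c(paste0("P", 1:5), paste0("SE", 1:5)))))
    }
    ind <- outer(1:5, q, "==") + 0            # 5 x n_cell indicator
    p <- drop(ind %*% w[in_cell]) / sum(w[in_cell])
    wrc <- wr[in_cell, , drop = FALSE]
    cs <- colSums(wrc)
    ok <- cs > 0   # a pure-BRR replicate can zero out a very small cell
    pr <- sweep((ind %*% wrc)[, ok, drop = FALSE], 2, cs[ok], "/")
    se <- vapply(1:5, function(k) brr_se(pr[k, ], p[k], design$fay_rho),
                 numeric(1))
    tibble(year = cells$survey_year[i], sex = cells$sex[i],
           age_group = cells$age_group[i], n = length(q),
           !!!setNames(as.list(c(p, se)),
                       c(paste0("P", 1:5), paste0("SE", 1:5))))
  })
  bind_rows(out)
}
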