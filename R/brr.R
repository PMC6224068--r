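#' Balanced repeated replication (BRR) weights and variance
#'
#' `brr_replicate_weights()` forms `R` replicate weights by half-sample
#' perturbation of the base sampling weights, optionally damped by Fay's
#' rho: a unit whose half-sample is selected in replicate `r` has its weight
#' multiplied by `2 - rho`, an unselected unit by `rho` (pure BRR,
#' `rho = 0`, gives the textbook doubled/zeroed weights). Half-sample
#' selection follows a Sylvester-Hadamard matrix of order `2^ceiling(log2(R))`:
#' replicates are its first `R` rows and each stratum is assigned an
#' odd-index column. Odd columns of a Sylvester matrix sum to exactly zero
#' over any even number of leading rows, so the replicate weights average
#' exactly back to the base weight for every unit.
#'
#' `brr_se()` turns replicate estimates into a standard error,
#' `sqrt(mean((theta_r - theta)^2) / (1 - rho)^2)`.
#'
#' @param design A tibble with columns `person_id`, `weight`, `stratum`
#'   (integer or factor) and `psu` (1 or 2 within stratum).
#' @param R Number of replicates; must be a multiple of 4. Default 500.
#' @param fay_rho Fay damping factor in `[0, 1)`; 0 is pure BRR.
#' @return `brr_replicate_weights()`: a `survey_design` list with `persons`
#'   (person_id, weight), a numeric `rep_weights` matrix (`n x R`), and
#'   `fay_rho`. `brr_se()`: a numeric standard error.
#' @export
#' @examples
#' d <- tibble::tibble(person_id = 1:4, weight = c(10, 12, 9, 11),
#'                     stratum = c(1, 1, 2, 2), psu = c(1, 2, 1, 2))
#' sd <- brr_replicate_weights(d, R = 4)
#' rowMeans(sd$rep_weights) - d$weight
brr_replicate_weights <- function(design, R = 500, fay_rho = 0) {
  stopifnot(is.data.frame(design),
            all(c("person_id", "weight", "stratum", "psu") %in%
                  names(design)))
  if (any(design$weight <= 0)) abort("base weights must be strictly positive")
  if (fay_rho < 0 || fay_rho >= 1) abort("fay_rho must be in [0, 1)")
  if (R < 4 || R %% 4 != 0) {
    near <- max(4, round(R / 4) * 4)
    abort(paste0("R = ", R, " is not a multiple of 4; nearest valid R is ",
                 near))
  }
  order <- 2^ceiling(log2(R))
  H <- hadamard_sylvester(order)
  strata <- as.integer(factor(design$stratum))
  n_strata <- max(strata)
  if (n_strata > order / 2) {
    abort(paste0("BRR construction of order ", order, " supports at most ",
                 order / 2, " strata; got ", n_strata))
  }
  if (!all(design$psu %in% c(1, 2))) abort("psu must be 1 or 2")
  # stratum h -> odd (0-indexed) column 2h - 1; replicates are rows 1..R
  cols <- 2L * strata           # 1-indexed column of the 0-indexed odd column
  sel <- H[seq_len(R), , drop = FALSE][, cols, drop = FALSE]  # R x n
  sign <- ifelse(design$psu == 1, 1, -1)
  mult <- 1 + (1 - fay_rho) * t(sel) * sign                   # n x R
  structure(
    list(persons = tibble(person_id = design$person_id,
                          weight = design$weight),
         rep_weights = design$weight * mult,
         fay_rho = fay_rho),
    class = "survey_design")
}

#' @rdname brr_replicate_weights
#' @param theta_reps Numeric vector of replicate estimates.
#' @param theta Full-sample estimate.
#' @export
brr_se <- function(theta_reps, theta, fay_rho = 0) {
  if (length(theta_reps) == 0) abort("no replicate estimates supplied")
  sqrt(mean((theta_reps - theta)^2) / (1 - fay_rho)^2)
}

# Sylvester-Hadamard matrix of order n = 2^k, entries +-1:
# H[i+1, j+1] = (-1)^popcount(i AND j)
hadamard_sylvester <- function(n) {
  if (n < 1 || bitwAnd(n, n - 1L) != 0) {
    abort("Hadamard order must be a power of two")
  }
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) {
    H <- rbind(cbind(H, H), cbind(H, -H))
  }
  H
}

#' @export
print.survey_design <- function(x, ...) {
  cat("<survey_design> ", nrow(x$persons), " persons, ",
      ncol(x$rep_weights), " BRR replicates, Fay rho = ", x$fay_rho, "\n",
      sep = "")
  invisible(x)
}
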