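test_that("quintile relative risks follow the log-linear dose-response", {
  expect_equal(quintile_rr(1), rep(1, 4))
  expect_equal(quintile_rr(0.77),
               c(2.496, 1.922, 1.480, 1.140), tolerance = 5e-4)
  expect_equal(quintile_rr(0.25, exponents = -0.5), 2)
  # for rr < 1, risks exceed 1 and decrease toward quintile 4
  rrs <- quintile_rr(0.6)
  expect_true(all(rrs > 1) && all(diff(rrs) < 0))
  expect_error(quintile_rr(0), "> 0")
})

test_that("paf_point matches a termwise brute-force evaluation", {
  expect_equal(paf_point(c(0, 0, 0, 0), 0.7), 0)   # all mass in quintile 5
  expect_equal(paf_point(c(0.2, 0.2, 0.2, 0.2), 1), 0)
  set.seed(4)
  for (i in 1:50) {
    p <- runif(4, 0, 0.25)
    rr <- runif(1, 0.3, 1.5)
    expect_equal(paf_point(p, rr), oracle_paf(p, rr), tolerance = 1e-12)
  }
  # a length-5 proportion vector is accepted, P5 ignored
  expect_equal(paf_point(c(0.2, 0.2, 0.2, 0.2, 0.2), 0.8),
               paf_point(c(0.2, 0.2, 0.2, 0.2), 0.8))
  expect_error(paf_point(c(-0.1, 0.2, 0.2, 0.2), 0.8), "nonnegative")
})

test_that("paf_point is monotone in rr and in mass shifted toward quintile 1", {
  p <- c(0.2, 0.2, 0.2, 0.2)
  rr <- seq(0.3, 1, by = 0.05)
  pafs <- vapply(rr, function(r) paf_point(p, r), numeric(1))
  expect_true(all(diff(pafs) < 0))
  # moving mass from quintile 5 into quintile 1 raises the PAF
  shift <- seq(0, 0.2, by = 0.04)
  pafs <- vapply(shift, function(s)
    paf_point(c(0.2 + s, 0.2, 0.2, 0.2), 0.7), numeric(1))
  expect_true(all(diff(pafs) > 0))
})

test_that("invert_rr is the exact inverse of paf_point", {
  p <- c(0.2, 0.2, 0.2, 0.2)
  expect_equal(invert_rr(p, 0), 1)
  set.seed(11)
  for (i in 1:40) {
    pp <- runif(4, 0.05, 0.25)
    rr <- runif(1, 0.2, 0.99)
    expect_equal(invert_rr(pp, paf_point(pp, rr)), rr, tolerance = 1e-8)
  }
  # a target above the PAF attainable at the bracket edge must error
  expect_error(invert_rr(p, 0.9, interval = c(0.5, 1)), "not attainable")
  expect_error(invert_rr(p, 1.2), "\\[0, 1\\)")
})

test_that("one inverted rr reproduces the published colorectal PAFs across cells", {
  props <- reference_quintile_proportions()
  pafs <- reference_pafs()
  cell <- function(yr, sx, ag) {
    r <- props[props$year == yr & props$sex == sx & props$age_group == ag, ]
    c(r$P1, r$P2, r$P3, r$P4)
  }
  anchor <- pafs[pafs$disease == "Colorectal cancer" &
                   pafs$age_group == "<15" & pafs$sex == "male", ]
  rr <- invert_rr(cell(2004, "male", "<15"), anchor$paf_2004 / 100)
  expect_equal(rr, 0.770, tolerance = 1e-3)
  checks <- list(
    list(2004, "female", "<15"), list(2015, "male", "<15"),
    list(2015, "female", "<15"), list(2004, "male", "35-54"))
  for (ck in checks) {
    printed <- pafs[pafs$disease == "Colorectal cancer" &
                      pafs$age_group == ck[[3]] & pafs$sex == ck[[2]], ]
    printed <- if (ck[[1]] == 2004) printed$paf_2004 else printed$paf_2015
    got <- 100 * paf_point(cell(ck[[1]], ck[[2]], ck[[3]]), rr)
    expect_lt(abs(got - printed), 0.2)
  }
})

test_that("Monte-Carlo PAFs degenerate to the plug-in value and bracket it otherwise", {
  p <- c(0.188, 0.186, 0.203, 0.219)
  mc0 <- paf_mc(p, 0.77, 0.77, 0.77, n_draws = 1000, seed = 1)
  expect_identical(mc0$paf, mc0$paf_plugin)
  expect_identical(mc0$ci_low, mc0$paf)

  mc <- paf_mc(p, 0.77, 0.70, 0.85, n_draws = 50000, seed = 3)
  expect_true(mc$ci_low < mc$paf && mc$paf < mc$ci_high)
  expect_equal(mc$paf, mc$paf_plugin, tolerance = 0.02)
  # determinism under a fixed seed
  expect_identical(mc, paf_mc(p, 0.77, 0.70, 0.85, n_draws = 50000,
                              seed = 3))
  # shrinking the CI tenfold per step drives the MC mean to the plug-in
  gaps <- vapply(c(1, 0.1, 0.01), function(sh) {
    est <- paf_mc(p, 0.77, 0.77 * (0.70 / 0.77)^sh,
                  0.77 * (0.85 / 0.77)^sh, n_draws = 20000, seed = 5)
    abs(est$paf - est$paf_plugin)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_error(paf_mc(p, 0.77, 0.80, 0.85), "ci_low <= rr")
})

test_that("paf_table crosses strata with diseases and respects sex applicability", {
  props <- subset(reference_quintile_proportions(), age_group == "<15")
  rr <- default_rr_table()[c(1, 8), ]   # colorectal + prostate (male only)
  tab <- paf_table(props, rr, n_draws = 200, seed = 2)
  expect_equal(sum(tab$disease == "Prostate cancer" & tab$sex == "female"),
               0)
  expect_gt(sum(tab$disease == "Prostate cancer" & tab$sex == "male"), 0)
  expect_true(all(tab$ci_low <= tab$paf & tab$paf <= tab$ci_high))
  expect_true(all(tab$paf < 1))
  # per-sex rr override scales the draws for that sex only
  rr2 <- dplyr::mutate(rr, rr_female = ifelse(disease == "Colorectal cancer",
                                              0.9, NA))
  tab2 <- paf_table(props, rr2, n_draws = 200, seed = 2)
  f <- tab2$sex == "female" & tab2$disease == "Colorectal cancer"
  expect_true(all(tab2$paf[f] < tab$paf[tab$sex == "female" &
                                          tab$disease == "Colorectal cancer"]))
})

test_that("paf_delta differences matched strata and is antisymmetric", {
  props <- reference_quintile_proportions()
  rr <- default_rr_table()[1, ]
  tab <- paf_table(props, rr, n_draws = 100, seed = 6)
  t04 <- tab[tab$year == 2004, ]
  t15 <- tab[tab$year == 2015, ]
  d <- paf_delta(t15, t04)
  expect_equal(d$paf_delta, t15$paf[match(paste(d$sex, d$age_group),
                                          paste(t15$sex, t15$age_group))] -
                 t04$paf[match(paste(d$sex, d$age_group),
                               paste(t04$sex, t04$age_group))])
  d_rev <- paf_delta(t04, t15)
  expect_equal(d$paf_delta, -d_rev$paf_delta)
  expect_equal(paf_delta(t04, t04)$paf_delta, rep(0, nrow(t04)))
  expect_error(paf_delta(t15[-1, ], t04), "mismatched strata")
  # published colorectal male <15 change: 32.1 - 36.7 = -4.6 points
  ref <- reference_pafs()
  row <- ref[ref$disease == "Colorectal cancer" & ref$age_group == "<15" &
               ref$sex == "male", ]
  expect_equal(row$paf_2015 - row$paf_2004, row$paf_delta, tolerance = 1e-9)
})

test_that("the default rr table is self-consistent with its anchors", {
  rr <- default_rr_table()
  expect_equal(nrow(rr), 13)
  expect_true(all(rr$ci_low <= rr$rr & rr$rr <= rr$ci_high))
  expect_equal(rr$sex_applicability[rr$disease == "Prostate cancer"],
               "male_only")
  # round trip: evaluating each rr on the anchor cell returns its PAF
  props <- reference_quintile_proportions()
  m04 <- props[props$year == 2004 & props$sex == "male" &
                 props$age_group == "<15", ]
  p <- c(m04$P1, m04$P2, m04$P3, m04$P4)
  anchors <- reference_pafs()
  anchors <- anchors[anchors$age_group == "<15" & anchors$sex == "male", ]
  got <- 100 * vapply(rr$rr, function(r) paf_point(p, r), numeric(1))
  expect_equal(got, anchors$paf_2004[match(rr$disease, anchors$disease)],
               tolerance = 1e-6)
})
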