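---
title: "Methods: diet-quality scoring and the attributable burden pipeline"
author: "dietburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet-quality scoring and the attributable burden pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietburden)
```

`dietburden` estimates the economic burden attributable to poor diet
quality with a prevalence-based, population-attributable-fraction (PAF)
approach, in four stages: score 24-hour dietary recalls with the HEI-C
2010; estimate the survey-weighted quintile distribution of the scores by
year, sex and age group with balanced-repeated-replication (BRR) variance;
convert quintile shares and meta-analytic relative risks into PAFs with
Monte-Carlo uncertainty; and attribute direct and indirect 2017-dollar
costs to those PAFs. Because the nutrition-survey microdata that motivate
this design are restricted, the package also includes a synthetic cohort
generator that emulates their structure, so every stage is testable end to
end.

## Diet-quality scoring

The HEI-C 2010 scores a diet on eleven components: eight *adequacy*
components (total vegetables and fruit, whole fruit, greens and beans,
whole grains, dairy, total protein foods, seafood and plant proteins, and
the fatty-acid ratio (PUFA+MUFA)/SFA) worth 60 points, and three
*moderation* components (refined grains, sodium, empty calories) worth 40,
for a 0-100 total. Every scorer is a clamped linear proration between a
minimum-score and a maximum-score standard:

* adequacy components score 0 at zero intake and the full points at the
  group standard (e.g. whole grains: 0 servings -> 0, the group standard
  (1.5-4 servings by age/sex) -> 10);
* the fatty-acid ratio scores 0 at 1.2 and 10 at 2.5;
* empty calories score 20 at or below 19% of energy and 0 at or above 50%;
* sodium scores 10 at or below the group Adequate Intake, 8 at the
  Tolerable Upper Intake Level, and 0 at twice the UL (piecewise linear in
  between) — this realizes the index's "8 to 10" maximum-point band;
* refined grains are a step: 10 points below 50% of grains refined, 0 at
  or above. The published standards leave no interval between the two
  thresholds, so a step is the faithful reading; a linear variant with
  configurable breakpoints is available (`refined_breaks`).

The published table prints serving standards as ranges spanning the
food-guide age/sex groups. The shipped standards table
(`default_hei_standards()`, also installed as
`extdata/hei_standards.csv`) resolves each group to a scalar inside the
printed range — children at the low end, adult males at the high end,
following the 2007 food-guide recommended servings. These per-group
scalars are editable placeholders within the printed ranges: the source
adaptation's exact values are not republished, so any table with the same
columns can be substituted. Serving standards are treated as absolute
servings per day by default; a per-1000-kcal density basis is available as
a configuration switch (`basis = "per_1000_kcal"`), since the US parent
index is density-based while the Canadian adaptation prints food-guide
serving counts.

Persons with more than one recall day are scored by summing amounts and
energy across days and computing ratios on the sums (the per-person
multi-day path of the NCI Simple Scoring Algorithm); ratio components are
then invariant to the number of days. Degenerate inputs have fixed total
rules: zero SFA with positive unsaturated fat is an infinite ratio (full
points); all fats zero scores 0; zero total grains means no refined grains
were consumed (full moderation points); zero summed energy marks the
person invalid.

## Quintile distribution and BRR variance

Scores are categorized into quintiles of the weighted score distribution.
Three pinned conventions make this reproducible:

* **Cutpoints** are the left-continuous inverse of the weighted ECDF
  (the weighted analogue of type-1 quantiles): the cutpoint at probability
  p is the smallest observed score whose cumulative weight share reaches p.
* **Bins** are right-closed: a score exactly on a cutpoint goes to the
  lower quintile.
* **Pooling**: cutpoints are computed from both survey years pooled (and
  from the full population, not per cell). Per-year cutpoints would force
  each year's quintile shares to 20% and hide any temporal change; pooled
  cutpoints let the high-quality (quintile 5) share drift between years,
  which is the quantity of interest. Per-year and reference-year policies
  remain available.

Variance uses balanced repeated replication. Replicate weights are built
from a Sylvester-Hadamard matrix of order `2^ceiling(log2(R))` (512 for
the default R = 500): replicates are the matrix's first R rows, and each
design stratum is assigned an odd-index column. Odd columns of a Sylvester
matrix sum to exactly zero over any even number of leading rows, so every
unit's replicate weights average back to its base weight exactly — the
truncation from 512 to 500 replicates costs nothing in balance. Fay's
damping factor is configurable and defaults to 0 (pure BRR, weights
doubled or zeroed).

`quintile_distribution()` re-estimates the cutpoints *inside every
replicate* before recomputing cell shares, so the standard errors carry
cutpoint-estimation uncertainty as well as share uncertainty; holding the
cutpoints fixed (possible via the lower-level `tabulate_proportions()`)
measurably understates the variance of year-on-year share changes.

## PAF with multiple exposure levels

Quintile 5 is the reference exposure. Given the meta-analytic relative
risk `rr` of quintile 5 versus quintile 1 (typically < 1), a log-linear
dose-response across quintiles gives the risk of quintile i relative to
quintile 5 as

$$RR_i = rr^{\,X_i - L},$$

with `X_i` the quintile mid-value (0.5, 1.5, 2.5, 3.5 on the
quintile-index scale) and `L = 4` the lower cut of quintile 5, so the
default exponents are (-3.5, -2.5, -1.5, -0.5). The PAF over the four
non-reference quintiles with shares `P1..P4` is

$$\mathrm{PAF} = \frac{S}{1+S}, \qquad
  S = \sum_{i=1}^{4} P_i\,(RR_i - 1).$$

This exponent convention is not arbitrary: the relative risk recovered by
inverting one published colorectal-cancer cell (male <15, 2004; PAF 36.7%)
under these exponents, rr = 0.770, reproduces the published colorectal
PAFs of four other independent cells (female <15 2004, male and female <15
2015, male 35-54 2004) to within 0.05 percentage points — the package's
acceptance script recomputes exactly this. Exponents remain configurable.

Uncertainty: the relative risk is treated as lognormal with
`sigma = (log(ci_high) - log(ci_low)) / (2 * 1.96)`; `paf_mc()` draws
50,000 values by default (plain Monte Carlo — there is no likelihood here
to run a chain over), reports the draw mean as the point estimate, the
2.5/97.5 percentiles as the CI, and always also reports the plug-in
`paf_point()`. With a degenerate CI the two coincide exactly. Every
estimate records its seed.

The default relative-risk table (`default_rr_table()`) is derived at run
time by inverting each disease's published male <15 2004 PAF, with a
synthetic ±15% log-scale CI band flagged `synthetic_ci`; substantive work
should supply the real meta-analytic table as a CSV. Per-sex override
columns (`rr_male`/`rr_female`) are honoured; prostate cancer is
male-only.

## Cost attribution

Direct costs per (disease, sex, age group) cell are
`sum over components (share x national component total)` for hospitals,
physicians and drugs, in constant 2017 CAD. Diabetes shares cover all
diabetes types, so diabetes cells are multiplied by 0.96 to isolate type
2 — at the direct-cost step, so indirect costs inherit the factor.
Indirect costs are disease-level indirect:direct ratios (a human-capital
valuation) times each cell's direct cost. Attributable burden is PAF x
cost per cell and year; all arithmetic is full precision, with rounding
only at serialization. Other-health-professional and unallocated
expenditures are excluded by design. Robustness toggles drop the under-15
strata or stomach cancer. The shipped cost tables
(`synthetic_cost_tables()`) are synthetic stand-ins with plausible scale
and structure only.

Sensitivity bounds re-run the plug-in pipeline with each disease's
relative risk set to its 95% bound: the bound nearer the null (rr = 1)
feeds the `low` report and the farther bound the `high` report, so the
two complete reports bracket the central one cellwise whatever the sign
convention of the risks.

## The synthetic cohort

The generator emulates two nutrition-survey cycles: respondent counts
default to the surveyed 35,107 (2004) and 20,487 (2015) with second-recall
fractions 0.307 and 0.37, a rough Canadian age pyramid over the food-guide
scoring groups, and a ~3% stream of records destined for the exclusion
filter (under-2s, pregnancy, breast-milk-only, invalid recalls). Intake
components are independent gammas per (year, sex, group) whose means are
tied to a person-level latent "quality" factor `q ~ N(year mean, 1)`;
a single `quality_shift` (default +0.35 SD in 2015) moves the whole score
distribution and is the generator's ground truth for temporal change.
Second recall days redraw day-level amounts around the same person means
(lognormal day noise, sd 0.2). The intake distribution parameters
themselves are package choices tuned once to give realistic score spreads
(cohort means near 60 with full use of the 0-100 range); no survey
publishes them.

The survey design carves every (year, sex, scoring group) cell into 8
pseudo-strata of two half-sample PSUs each (192 strata in all). This
matters: with one stratum per cell, a cost-age cell's BRR variance
estimate has only one or two squared half-sample differences behind it,
and normal-quantile confidence intervals undercover badly. Many small
strata — as in real national survey designs — give the variance estimator
its degrees of freedom; with them, the recovery study below covers at
nominal rates.

What the generator does *not* emulate: food-coding from raw nutrition
files, nonresponse adjustment, intra-household clustering, seasonal and
weekday recall effects, and correlated measurement error between
components. Passing tests therefore demonstrate that the estimation
machinery is correct under a known data-generating process, not that the
shipped defaults reproduce any real population's intake distribution.

## Validation and problem sizes

The test suite validates each stage against independent oracles:
brute-force weighted-ECDF quantiles, termwise PAF sums, interpolation
through the printed scorer breakpoints, the closed-form stratified SE of a
weighted mean (for strata with equal within-pair weights the BRR variance
is exactly `sum(w_h^2 d_h^2) / sum(w)^2`), and round-trip
`invert_rr(paf_point(.))` identities. Published-table consistency checks
re-derive the colorectal relative risk and re-aggregate the published
burden table's marginals (which carry $1-2 independent-rounding artifacts,
hence $10 tolerances).

The parameter-recovery study runs the full pipeline on 20 cohorts of
1,500 respondents per year against ground truth measured on a 12,000-
per-year cohort, and asks that the estimated quintile-5 share change per
(sex, age group) cell cover the truth within its 1.96-SE BRR interval in
at least 90% of cells; observed coverage is ~94%. These problem sizes are
the package's own choice for a fast default validation run; the generator
happily produces survey-scale cohorts.

## Known limitations

* The shipped scoring standards are placeholders within the printed
  ranges; group-level scores shift if the true adaptation used different
  scalars (quintile-based results are less sensitive, being rank-based).
* Quintile boundary ties go to the lower quintile by convention; with
  continuous synthetic scores ties are measure-zero, but coarsely rounded
  input scores would make the convention visible.
* The Monte-Carlo CI propagates relative-risk uncertainty only — not
  quintile-share sampling error; the BRR machinery quantifies the latter
  separately, and the two are not combined.
* Costs are a single year's prevalence-based snapshot in constant 2017
  CAD; incidence-based lifetime costing is out of scope.
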