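---
title: "Raking weights for loyalty-card cohorts: model, assumptions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raking weights for loyalty-card cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartrake)
```

## The setting

A retailer's loyalty-card program records, for every consenting member, each
grocery purchase with a timestamp, a product-group code, expenditure in EUR
and weight in kg. Members who consent to release these records form a
*volunteer* cohort: selection into the cohort correlates with sex, age,
education and occupational status, so raw cohort summaries misrepresent the
adult population. The statistical task has three parts:

1. **characterize** the selection bias by comparing cohort sociodemographic
   margins to census margins;
2. **correct** it with poststratification weights built by raking;
3. **validate** the cohort's self-reported degree of loyalty (the share of
   all grocery spending made at the focal retailer, on a five-band ordinal
   scale) against behaviour actually observed in the transactions, via RFM
   scores, and describe food-group purchases weighted and unweighted.

## Raking

### Model

Let unit $i$ in the sample fall in cell $c_m(i)$ of margin $m$, where each
margin is a one-way or two-way contingency table of population counts
$T^m_c$. Raking seeks weights $w_i \ge 0$ with
$\sum_{i : c_m(i) = c} w_i = T^m_c$ for all cells of all margins. The
algorithm initializes all weights equal to (population total / sample size)
and repeatedly sweeps the margin list; for margin $m$ each unit's weight is
multiplied by $T^m_{c_m(i)} / \widehat{T}^m_{c_m(i)}$, the ratio of the
target to the current weighted total of its cell. This is the unit-level
analogue of classical cell-level IPF, and where units are exchangeable
within cells the two coincide — a property the test suite checks against an
independently coded cell-level IPF on random seed tables. Matching two-way
margins (sex x age, sex x education, age x education, ...) calibrates joint
distributions, which matching one-way margins separately cannot do.

### Convergence, tolerances

The sweep repeats until the maximum relative discrepancy over all margin
cells is at most `tolerance` (default `1e-7`) or `max_iterations` (default
200) is reached. These defaults are conventional survey-calibration values;
at cohort scale (tens of thousands of units, nine margins) convergence
takes well under a second. Non-convergence returns the weights with
`converged = FALSE` and a warning rather than an error, because a
nearly-converged weight vector is still diagnosable. A sample cell that is
empty while its target is positive is a hard error — no unit can carry that
mass, and smoothing it away would silently change the estimand. The margin
sweep order is the configured list order; the fixed point does not depend
on it, and a test asserts order-invariance rather than assuming it.

### Trimming and rescaling

Extreme weights inflate variance, so after raking each weight is clamped
into `[0.1, 10]` (configurable). Trimming happens **once, with no
re-raking**, and is followed by rescaling so the weights sum to the number
of weighted-eligible participants. Trimmed margins therefore match targets
only approximately — this mirrors how such weights are reported in practice
("match well", not exactly). Whether rescaling should precede trimming is
genuinely open; the package defaults to trim-then-rescale and exposes
`rescale_before_trim` in `raking_control()` for the other order.

A scale subtlety: margins arrive as population counts (millions), while
trim bounds of 0.1 and 10 are meaningful for weights on the *relative*
(mean-1) scale — a published untrimmed range of roughly 0.04 to 82 only
makes sense there. `rake()` is literal (weighted totals equal the margins
as given); `two_phase_weights()` therefore rescales each phase's margin
targets to that phase's sample size before raking, so the trim bounds act
on mean-1 weights. Only the weights' ratios matter downstream.

### Two-phase missingness handling

Sex and age come from the retailer's register and are nearly complete;
education, marital status, occupation and the children indicator come from
a questionnaire with roughly 22% nonresponse. Weights are therefore built
in two phases: phase 1 rakes the complete cases over the full margin set;
phase 2 rakes the *whole* eligible sample over sex x age only, and its
weights are assigned just to the units that were incomplete on the full
margins. The combined vector is trimmed, then rescaled to the eligible
count. Units missing sex or age receive no weight and are reported. A
consequence worth knowing: the combined weighted sex/age margins retain a
small residual (well under a percentage point in our tests) because the
phase-2 calibration is computed jointly but assigned selectively; fully
raked variables like education are matched exactly for the complete cases
that carry them.

## The synthetic cohort generator

The generator states a world with the features the analysis assumes, at
desk scale:

* a reference population whose sex and age margins follow the national
  adult distribution (women 51.12%; six age bands from 18.04% at <=29 to
  18.20% at >=70), with education, occupation and marital status drawn
  conditionally on age and the children indicator conditional on age and
  marital status — this sequential scheme reproduces the two-way structure
  raking calibrates against without a full joint specification;
* logistic consent with intercept `qlogis(0.04)` (the observed ~4% consent
  rate) and positive coefficients for women, the higher-educated and the
  employed, negative for under-30s and over-70s — the documented direction
  of volunteer bias;
* completely-at-random questionnaire nonresponse at 22% by default (the
  observed rate), with an optional covariate-dependent mechanism since the
  true mechanism is uncharacterized; a `21/47066` rate of missing register
  sex/age, matching the handful of unweightable units;
* five loyalty classes with the observed cohort shares (6.25/12.79/16.85/
  25.25/38.86%), each with a spending multiplier (0.30-1.92, from the
  observed fivefold gradient in total purchases); the self-report is
  recovered by binning the true focal share, so class and report agree;
* per food group, a Bernoulli zero-inflation (3-26%, e.g. 26% never buy
  skimmed milk) and log-normal 2-year totals whose medians equal the
  published unweighted medians, split over `1 + Poisson` purchase events
  with uniform timestamps; the event rate also scales with the loyalty
  multiplier, because an RFM gradient requires frequency and recency — not
  just totals — to vary with loyalty;
* a 0.5% never-purchaser rate (99.5% of participants buy at least one
  item).

What the generator does **not** emulate: store geography, product-level
(rather than group-level) baskets, price inflation, household dynamics,
seasonality. A green end-to-end test therefore establishes that the
weighting machinery corrects the *kind* of bias stated above — not that it
would correct any real cohort's bias, whose selection mechanism may depend
on variables no margin captures.

Scale is the one stated-world parameter that had to move: the real cohort
(47,066 consenters against a 4.4M population) is not reproducible on a
desk, and with a few thousand consenters rare two-way cells (e.g. widowed
under-30s) are empty, violating raking's own precondition. The default
population is 200,000 (about 10,000 consenters), the smallest round size at
which all nine paper-style margins are safely populated; tests use smaller
cohorts with reduced margin sets via `margin_pairs`.

## RFM scores

Recency (days from last purchase to the reference date, default the end of
the observation period), frequency (distinct purchase events, i.e. distinct
(participant, timestamp) pairs; line-item counting is available), and
monetary value (total EUR) are each binned into sample quintiles via
average ranks (`ceiling(5r/n)`); a constant dimension puts everyone in the
middle bin 3. The composite score is `100R + 10F + M`, the only composition
consistent with three-digit scores bounded by 555. Ties share bins;
monotone transforms of a dimension leave its bins unchanged.

## Food-group summaries and weighted quantiles

Transactions are mapped from product-group codes to seven study food groups
(vegetables; skimmed milk & sour milk; sugar-sweetened beverages; rye
bread; red meat & processed meat; fat spreads; sweets & chocolate), with
everything else `unassigned`; the coverage report states the assigned share
of the taxonomy to one decimal. Per participant, 2-year totals in EUR and
kg per group, and shares of the all-grocery totals, are summarized as
`median [IQR]`.

The weighted quantile is the left-continuous cumulative-weight inverse: the
smallest value whose cumulative normalized weight reaches $q$. It is
deterministic, scale-invariant in the weights, and reduces with equal
weights to the order statistic at $\lceil qn \rceil$. For internal
consistency the *unweighted* summary columns use the same estimator with
unit weights — so equal weights reproduce the unweighted table exactly —
rather than the interpolating even-$n$ median convention; for the skewed,
heavily-tied purchase distributions at cohort sizes the difference is
negligible, and the reweighting effect is reported as
`100 * (weighted median / unweighted median - 1)` to one decimal.
Participants with a zero all-grocery total have undefined shares and are
excluded from share summaries (and reported). Whether group medians should
be computed over all participants or only purchasers of the group is
ambiguous in practice; both modes exist (`mode = "all"` default,
`"purchasers"`).

## Group comparisons

Sociodemographic distributions across the five loyalty groups are compared
with Pearson's chi-square (no continuity correction, asymptotic p-values —
appropriate at cohort scale; exact permutation enumeration exists in the
test suite as an oracle, not as a user path). Purchase variables use
Kruskal-Wallis with tie correction, the right choice for strongly
right-skewed, zero-inflated totals. RFM scores are compared with both
one-way ANOVA and Kruskal-Wallis, since either is defensible for bounded
discrete scores and published F-statistics suggest ANOVA was used for them;
the package emits both and privileges neither. Weighted group comparisons
are descriptive only (weighted medians, no weighted tests), because
design-based testing would require variance machinery (replicate weights)
that is out of scope.

## Degenerate inputs and tie-breaks

* Loyalty shares exactly on a bin edge (20/40/60/80%) go to the
  lower-labelled bin: the printed labels are closed intervals.
* `total_spend = 0` yields a missing loyalty category.
* A margin with a zero cell loads but is flagged not rakeable; validation
  is report-based, raking refuses on blocking issues.
* A single participant's RFM bins are all 3 by the constant-dimension
  convention.
* Groups with no observations are dropped with a warning and reduced df.

## Known limitations

* Margins of dimension >= 3, design weights, GREG/continuous calibration
  and variance estimation are not implemented.
* Trimming is not re-raked, so trimmed weights do not exactly reproduce
  margins; the residual is reported, not corrected.
* The two-phase residual on reduced-margin variables (see above) is
  inherent to the method, not a bug.
* The generator's selection mechanism is logistic in observed covariates;
  it cannot represent selection on unobservables, so "bias corrected" in
  tests means bias *of the stated form*.
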