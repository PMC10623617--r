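---
title: "Weighted continuous norming: model, design choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted continuous norming: model, design choices, and what the simulations show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Norm-referenced psychometric tests convert a raw score into a norm score
(here on the IQ metric, mean 100, SD 15) relative to an age-specific
reference population.  When the normative sample is not demographically
representative -- say, highly educated families are undersampled -- the
estimated norms are biased for everyone.  `wcnorm` implements *weighted
continuous norming* (WCN): semi-parametric continuous norming (SCN)
combined with post-stratification weights obtained by raking (iterative
proportional fitting), so that the weighted sample marginals match the
population's demographic marginals.  The package also contains a complete
simulation framework for studying when weighting helps, does nothing, or
hurts.

## The norming procedure

Given a normative sample with one row per person (age, raw score,
demographic categories) the pipeline is:

1. **Raking** (`rake_weights()`): starting from unit weights, each
   demographic variable's category weights are rescaled in turn so the
   weighted marginal matches its population target, and the sweep is
   repeated until no marginal deviates by more than `tol` (default
   `1e-6`, at most `max_iter = 50` sweeps; on a 3x3x3 problem a handful
   of sweeps suffice).  Weights are then standardized
   (`standardize_weights()`) so the most overrepresented group has
   weight exactly 1; this changes no weighted proportion and no weighted
   fit, it only makes weights readable.  Joint-distribution targets can
   be raked by recoding a cross-classification into one variable whose
   levels are the joint cells.
2. **Weighted ranking** (`weighted_percentile_ranks()`): within each
   one-year cohort every person receives the weighted tie-averaged
   mid-rank percentile
   \[ p = \frac{W_{below} + 0.5\,W_{equal}}{W_{total}}, \]
   where the \(W\) are sums of weights over persons with lower / equal
   raw scores.  With unit weights this is exactly the RankIt rule
   \((\textrm{mean rank} - 0.5)/n\) with tie averaging, which pins down
   the generalization: the unweighted procedure (SCN) is the equal-weight
   special case, bit for bit.  The percentile is mapped to the person
   location \(\ell = 100 + 15\,\Phi^{-1}(p)\).
3. **Model fitting** (`fit_norm_model()`): raw score is regressed on a
   polynomial in location and age by weighted least squares over the
   candidate terms \(\ell^i a^j\), \(0 \le i, j \le k\), excluding the
   constant pair -- with the default `k = 4`, 24 candidates.  For each
   size up to `max_terms = 12` a stepwise search with single-term
   replacement minimises the weighted residual sum of squares
   (approximating exact best-subset selection); the final model is the
   smallest size whose adjusted R-squared reaches `r2_target = .99`
   *and* whose predicted raw score is non-decreasing in \(\ell\)
   everywhere on a 200 x 60 (location x age) grid over the calibration
   range.  If no size meets both, the best monotone candidate is
   returned and flagged.
4. **Inversion** (`predict_norm_score()`): a person's norm score is the
   \(\ell\) solving \(\hat{raw}(\ell, age) = raw\), found by bisection
   to `1e-4` IQ points (far below the 1-IQ-point granularity of printed
   norm tables).  The polynomial is inverted only over the location
   range it was calibrated on; beyond it the prediction is continued
   *linearly* with the boundary slope up to IQ 40-160, because
   extrapolating a quartic outside the data is meaningless and
   occasionally wild.  Raw scores outside the attainable range are
   clamped to the interval end; extrapolated and clamped scores are
   flagged.  Norm scores are never rounded internally; rounding to
   integers happens only in the norm-table export.

### Numerical choices

* **Age predictor.** The regression uses the cohort midpoint
  (`cohort + 0.5`) rather than exact age, because locations are
  estimated per cohort and carry no within-cohort age information;
  predictions at arbitrary continuous ages interpolate across cohorts.
  `age = "continuous"` is available.
* **Bracketing for inversion.** Before bisecting, predictions are
  evaluated on a unit-step location grid over the calibration range and
  a running maximum is taken; the root is bisected inside the bracketing
  grid cell.  For a monotone model this changes nothing; combined with
  the linear continuation outside the calibration range it keeps the
  inversion defined, bounded and monotone everywhere.
* **Degenerate inputs.** A cohort (or benchmark age group) containing a
  single distinct raw value maps it to percentile 0.5, i.e. IQ 100, and
  benchmark groups of that kind are counted and reported.
* **Tie handling.** Ties in raw scores always receive the average rank
  (weighted mid-rank); ties in continuous age are measure-zero and
  broken by position when forming benchmark age groups.

## The simulation world

The generator reproduces the study conditions end to end; its defaults
*are* those conditions and are not tuned.

**Ability surface.** Three demographic variables -- education, ethnicity,
region -- each have three categories coded 1 (above-average ability) to 3
(below-average): high/medium/low education, non-native/mixed/native
ethnicity, northwest/east/south region.  The mean latent ability of a
demographic cell at age \(a\) is

\[ M = -1.5e - 0.25t - 0.1r - 0.05tr + 1.2a - 0.06a^2 + 0.0001a^4 , \]

and individual abilities are \(x_1 = M + z\), \(z \sim N(0,1)\), with age
uniform on [0, 6) over six one-year cohorts.  With the reference
marginals below, covariance algebra gives a within-age education-ability
correlation of -.78 (verified against the simulation in the test suite);
the ethnicity and region coefficients imply much weaker correlations
(about -.17 and -.10), so education dominates the norming bias.  Codes
were chosen so that this -.78 design value is reproduced; the coding
itself is otherwise arbitrary.

**Populations.** The reference population (scenario 1) crosses the
marginals education 40/20/40, ethnicity 30/40/30, region 60/20/20
(percent, in code order) into 27 independent cells.  Five biased
populations perturb it:

| id | manipulation | education marginal (low/med/high) |
|----|--------------|-----------------------------------|
| 2  | mild underrepresentation of high education | 52/20/28 |
| 3  | moderate underrepresentation | 60/20/20 |
| 4  | both tails underrepresented | 30/40/30 |
| 5  | joint cells biased, all marginals exact | 40/20/40 |
| 6  | clustered: per cohort only 9 cells populated | 40/20/40 pooled |

Scenario 5 adds \(c\cdot f(e)f(t)f(r)\) percentage points per cell with
\(f = (+1, -2, +1)\) and \(c = 0.15\) -- the largest magnitude keeping
every cell non-negative given the 1.6 % centre cell.  The pattern's
marginal sums are identically zero, so it biases only joint cells; it
overrepresents the extreme-ability corner cells (variance up, mean almost
unchanged).  Scenario 6 activates 9 of 27 cells per cohort at triple
their reference proportion, rotating three fixed blocks so each is active
in exactly two cohorts; pooled over cohorts the population equals the
reference exactly.  No partition of the reference cells into three
equal-probability blocks exists (cell masses are multiples of 0.4 %,
totalling 250 such units), so the blocks were fixed once by a randomized
search that balances block mass (33.2/33.2/33.6 %) and block mean
ability; cohort tables consequently sum to 99.6-100.8 % and are
normalized implicitly when sampling.  Balancing block *means* matters:
the clustered condition is meant to perturb per-cohort ability variance,
not per-cohort means, which no age polynomial could absorb.

**Standardization.** Abilities are z-standardized with the *reference*
population's moments (`reference_moments()`, empirically ~sd 2.28, which
matches the closed-form value used as a test oracle), for every
population.  Biased populations therefore have nonzero standardized
means -- e.g. scenario 2's mean is negative because high-ability cells
are undersampled -- which is precisely the bias the norming methods face.

**Test scores.** A single 31-item 1-PL (Rasch) test is simulated per
experiment: difficulties drawn once from Uniform(-3, 3) and shared by all
populations, replicates and the benchmark (per-replicate banks would
confound the method comparison).  Item responses are Bernoulli with
\(p = \textrm{logistic}(\theta - \delta_i)\), summed to a raw score in
0..31.  The bank is a random draw, and tail errors depend noticeably on
how well its difficulties cover the ability range -- one source of
between-seed variation in the headline numbers.

**Benchmark norms.** `compute_iq_best()` sorts each cohort by age,
splits it into 365 equal-sized groups (2,190 overall), and assigns each
raw score its within-group mid-rank inverse-normal IQ.  This empirical
IQ\(_{best}\) converges to an analytic oracle (`analytic_iq_best()`, a
27-cell mixture of Poisson-binomial distributions integrated over the
ability distribution by quadrature), which the test suite checks at two
population sizes.  At the reduced reference sizes used here the finite
group size adds noise to IQ\(_{best}\) (about 0.6 IQ points RMS at the
centre and 1.8 at the tails for a 2.4M reference); this inflates measured
RMSE slightly but cancels in MSD.

**Evaluation.** Every fitted model is scored on one fixed, seed-controlled
subsample of 20,000 reference-population evaluees carrying IQ\(_{best}\)
-- *reference*-distributed regardless of which population the norm sample
came from, because person-location bins across the whole ability range
must stay populated.  The source study does not state which individuals
enter its error formulas; this choice is our interpretation, and
in-sample evaluation remains possible by scoring a model on any sample.
Errors are summarised as RMSE and MSD (predicted minus benchmark, IQ
points), overall and within 11 bins of 7.5 IQ points centred 62.5 to
137.5, then averaged: replicates within bin, bins within population,
populations.  Bootstrap percentile intervals over replicates quantify
Monte-Carlo uncertainty in place of the original ANOVA machinery, and a
1-IQ-point practical-relevance flag marks contrasts that would survive
rounding to integer IQ scores.

## Problem sizes

Full scale is 4M persons per cohort and 100 replicate samples of 600 per
population.  The package's own studies run reduced profiles: the
acceptance script uses 400k per cohort (2.4M persons) with 50 replicates,
and the test suite 400k per cohort with 30 replicates; both finish on one
CPU in minutes.  The reduction leaves MSD essentially untouched and adds
the benchmark noise quantified above to RMSE.

## What passing simulations do and do not show

The generator emulates the study conditions: independent demographic
cells, a polynomial mean surface, unit within-cell variance, a single
unidimensional 1-PL test, and one-year cohorts over ages 0-6.  Real
normative data differ in ways that matter: demographic variables interact
in their effect on ability; items need not fit a 1-PL model; raw-score
distributions can have floors, ceilings and skew beyond what 31 uniform
items produce; sampling is rarely exactly stratified; and age ranges and
group sizes vary.  Passing results here therefore show the *mechanism* --
raking corrects marginal underrepresentation of a strongly ability-linked
variable, does little when only joint distributions are biased, and can
amplify tail noise when both ability tails are undersampled -- not a
guarantee of the same effect sizes on real data.

Known limitations:

* Weighted norming inherits raking's blind spot for joint-distribution
  bias; joint targets require the recoding device described above.
* Models are polynomials: behaviour outside the calibration range is
  extrapolation, and the monotonicity audit covers only the calibration
  grid.  Errors concentrate in the outer location bins, where normative
  samples of 100 per cohort contain one or two informative observations.
* The error-measure magnitudes reported by the simulation depend on the
  random item bank and on tail behaviour of the selected polynomials;
  contrast *directions* between methods are stable across seeds, absolute
  levels less so.
* No parametric (GAMLSS-style) continuous-norming comparison, no
  confidence intervals on individual norm scores, no variance estimation
  for survey totals, and no weight trimming (none is applied in the
  procedure modelled here).
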