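---
title: "Designing sparse test-day recording regimes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sparse test-day recording regimes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genetic improvement of dairy cattle in low-resource (tropical) sectors is
limited by milk recording: weekly or even monthly test-day (TD) visits for
every cow are unaffordable, yet lactation yields are needed to estimate
breeding values and run progeny testing. `tdregimes` asks how few — and
how *timed* — TD records per lactation still support accurate yield
estimation and selection, using a fully simulated Sahiwal-like herd in
which the true yields are known.

# The simulation model

Daily milk yield of cow $i$ at day in milk $t$ follows the Wood
incomplete-gamma curve with additive noise:

$$y_{it} = \exp(k_i + b_i \log t - c_i t) + \varepsilon_{it},
\qquad \varepsilon_{it} \sim N(0, \sigma_\varepsilon^2),$$

on $t = 1, \dots, L$ with $L = 280$ days (typical Sahiwal lactations are
shorter than 305-day standards). The curve-shape triple $(k_i, b_i, c_i)$
decomposes additively into scenario fixed effects, a polygenic triple
correlated across cows through the numerator relationship matrix
$\mathbf{A}$ (the stacked genetic vector is
$N(\mathbf{0}, G \otimes \mathbf{A})$), and an independent cow
environmental triple $N(\mathbf{0}, E)$ with diagonal $E$. The true
lactation yield is the sum of the $y_{it}$, noise included; a noise-free
curve total is stored alongside (`curve_yield`) for users who prefer the
noiseless definition.

Two scenario presets bracket realistic curve shapes: `APHP` (k0 = 1.442,
b0 = 0.170, c0 = 0.005; peak 6.5 kg/day at 34 DIM, persistency 0.42) and
`HPLP` (k0 = 1.121, b0 = 0.350, c0 = 0.010; peak 7.5 kg/day at 35 DIM,
persistency 0.18). The pedigree generator mirrors a progeny-testing herd:
82 unrelated sires with 464 recorded daughters (5.66 daughters/sire on
average), dams unknown — a paternal half-sib design two generations deep.
Real pedigrees are deeper; `pedigree()` accepts arbitrary valid pedigrees
when more structure is available.

## Variance-component defaults and calibration

No public reference values exist for $G$, $E$ and
$\sigma_\varepsilon^2$ in this breed, so the package derives its own
defaults and documents them:

* $E = \mathrm{diag}(0.11, 0.040, 0.0010)^2$ — cow-level environmental
  spread giving a phenotypic coefficient of variation for total yield
  near 30%, the level reported for unimproved tropical herds.
* $\sigma_\varepsilon^2 = 1.44$ kg² (1.2 kg/day): chosen so the
  test-interval method at weekly recording has a mean square error of
  prediction near $3\,000$ kg², the error scale reported for that
  reference protocol; a weekly TIM estimate is a weighted sum of 40 noisy
  records with ~7-day weights, so its error variance is
  $\approx 1960\,\sigma_\varepsilon^2$.
* $G$: a base matrix (genetic SDs 0.06, 0.022, 0.00055; correlations
  $r_{kb} = -0.4$, $r_{kc} = -0.3$, $r_{bc} = 0.7$, the sign pattern of
  published Wood-parameter fits) rescaled by `calibrate_varcomps()` so
  the realized heritability of cumulative 280-day yield is 0.2. The
  calibration is a root find over the scale of $G$ using common random
  numbers; the frozen factor is 2.6937
  (`calibrate_varcomps(target_h2 = 0.2, n = 50000, seed = 20140078)`).

"Realized heritability" here is the Monte-Carlo ratio of the variance of
genetic-only curve totals to the total phenotypic variance in a large
unrelated population. Because total yield is a *convex* function of the
parameter triple, between-family resemblance in a pedigreed population is
slightly inflated relative to this definition, and animal-model REML
estimates of $h^2$ on simulated 464-cow herds centre near 0.21–0.22
rather than 0.200. Both views are exercised by the test suite; the
discrepancy is a property of the exponential observation model, not an
estimation defect.

Negative daily yields (rare at these settings; ~0.04% of records) are
floored at 0.01 kg and counted (`n_floored`), because curve fitting on
records requires positive yields.

# Yield estimation

Two estimators reduce a handful of TD records to a lactation yield:

* **Test-interval method** (`tim_yield()`): the reference field method.
  Each interval between consecutive TDs is credited with the mean of its
  bounding yields; the edges are credited at the first and last recorded
  yields. With records on every day this reproduces the daily sum up to
  the trapezoid end correction $(y_1 - y_L)/2$.
* **Wood-model fitting** (`fit_wood()`): fit the curve, then sum its
  fitted values over days 1..L.

Wood fitting deserves care. The log-linear form
$\log y = k + b \log t - c t$ is attractive (three-parameter linear
solve), but at realistic noise the retransformation to the natural scale
is badly biased: $\exp$ of an unbiased fit of $E[\log y]$ underestimates
$E[y]$, and the distortion varies along the lactation. Measured on the
default population, a log-scale mixed fit at quarterly recording had
three times the MSEP of TIM, inverting the scientific conclusion. The
package therefore fits the *natural-scale* model:

* `mode = "hierarchical"` (default): a two-stage empirical-Bayes fit.
  Stage 1 estimates each cow's triple by damped Gauss–Newton (log-linear
  start). Stage 2 re-fits each cow at its posterior mode under a working
  normal prior whose mean, between-cow covariance (method-of-moments:
  observed spread minus average sampling covariance) and residual
  variance come from stage 1. This reproduces the shrinkage of a
  nonlinear mixed model — essential when 4 records estimate 3
  parameters — at about 30 ms per regime for 464 cows, which is what
  makes the regime search feasible.
* `mode = "nlme"`: the full nonlinear mixed-effects model, the reference
  estimator (tens of seconds per fit). On the default population its
  quarterly MSEP (25.7k kg²) agrees with the empirical-Bayes fit
  (26.3k kg²).
* `mode = "percow"`: the plain log-linear per-cow OLS, kept because it is
  exact on noiseless records and useful diagnostically.

Accuracy of any estimator is summarised by `score_estimates()`: MSEP,
bias (mean of estimated − true) and $\sigma_\Delta$ (SD of estimated −
true, the increase in residual SD attributable to the protocol).

# Searching for strategic regimes

`run_search()` implements an iterative pool-elimination search for
$m$-day regimes (m = 4, 5, 6): draw random regimes from the current pool
of DIM until every pool day appears in at least 25 regimes (the coverage
default; scaled-down runs use 5), score each regime by Wood-model MSEP,
average MSEP per day over the regimes containing it, and drop the worst
quarter of the pool ($\lceil n/4 \rceil$ days, ties broken by removing
the later day) before the next loop. Ten loops shrink 280 candidate days
through 280, 210, 157, …, 27 to 20. The best regime is tracked across
all loops, since late loops draw from better pools but fewer
combinations.

One numerical guard matters: regimes with all days clustered in one part
of the lactation can drive the curve fit into absurd extrapolations
(totals of millions of kg). Left unchecked, such catastrophic MSEPs
poison the per-day averages — whole regions of the lactation get blamed
for the failures of clustered regimes, and the pool collapses onto early
days. A per-cow fit is therefore declared failed when its total is
non-finite, negative, or above 3 × L × the cow's best observed day
(no cow plausibly sustains three times its observed peak for the whole
lactation); a regime whose fits fail for more than 10% of cows is
discarded and logged rather than scored. With this guard the per-loop
median MSEP declines over the loops and the selected pools span early,
mid and late lactation.

# Genetic evaluation and planning

`blup_ebv()` solves Henderson's mixed-model equations for the
single-trait animal model $y = \mathbf{1}\mu + Za + e$,
$a \sim N(0, \mathbf{A}\sigma_A^2)$, with one overall mean — the
scenario's month/year/age effects enter through the simulator and are
identical for all cows, hence not estimable. Variance components default
to known-truth mode ($h^2$ supplied, default the design value 0.2) to
isolate regime comparison from estimation noise; `reml_h2()` provides
the REML estimate (eigendecomposition of the observed-animal
$\mathbf{A}$ submatrix makes the profile likelihood a 1-D optimisation)
for end-to-end runs. Because the MME coefficient matrix does not depend
on the phenotypes, `blup_solver()` factorises it once and scores
thousands of regimes by triangular backsolves.

Ranking agreement uses `top_k_overlap()` (animals shared between the
top-100 of a regime's EBVs and the true EBVs; ties broken by id) and
`ebv_correlation()`.

`plan_table()` translates accuracy into progeny-testing capacity through
selection-index theory: reliability of a sire with $d$ daughters,
$R = d h^2 / (4 + (d-1) h^2 + 4 \sigma_\Delta^2 / \sigma_P^2)$, its
closed-form inversion for the daughters required at target reliability,
and `budget / (m d)` sires testable within a national recording budget
(default 7500 = 30 farms × 25 cows × 10 records). $\sigma_P^2$ is always
the empirical variance of the simulated true yields. Daughters are kept
continuous by default (an integer mode rounds up), matching how such
tables are conventionally reported.

# Recommended windows

Regimes whose Top-100 overlap with the true EBVs *exceeds* 80 qualify as
"accurate enough for selection". Across qualifying m-day regimes, the
j-th smallest day forms the position-j distribution; its median and
central quarter (the 37.5th–62.5th percentile band — the "middle 25%"
convention, chosen as the literal central quarter and isolated in one
place should another reading be preferred) are the recommended windows.
`ks_uniformity_test()` checks each position against the exact j-th of m
uniform order statistic on (0, L) — the $L \cdot \mathrm{Beta}(j, m+1-j)$
law — to confirm the windows are genuinely strategic rather than what
uniform random sampling would produce. Days are integers, so ties make
the KS p-values approximate; at the sample sizes involved this is
immaterial.

# Problem sizes, determinism and limitations

The shipped tests exercise the full herd size (82 sires, 464 cows,
280-day lactations) for estimation, evaluation and the searches, with
per-day coverage 5 (instead of 25) and single seeded replicates for the
search-based checks; variance-component checks use 2,000–20,000-cow
Monte-Carlo populations and 20–48 replicate REML fits. Every stochastic
function takes a seed, and `run_pipeline()` derives named substreams
(`pedigree`, `population`, `search`) from one master seed so any stage
reproduces in isolation.

What the simulation does *not* emulate: serially correlated daily
residuals (real milk records are autocorrelated; errors here are
independent by design), multiple lactations per cow, month/year/age
variation within a population, missed visits or recording error in DIM,
and deeper maternal pedigree. Passing tests therefore demonstrate the
machinery and the qualitative orderings under the stated model, not
field performance of any particular calendar. The planning formulas
inherit the usual selection-index idealisations (unselected daughters,
one record each, known variances).
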