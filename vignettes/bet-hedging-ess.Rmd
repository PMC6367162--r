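---
title: "Methods: evolutionarily stable germination fractions from precipitation responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionarily stable germination fractions from precipitation responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bethedgr)
library(dplyr)
```

## The model

Desert winter annuals hedge their bets: only a fraction `g` of a species'
seed bank germinates each autumn, and the remainder waits out the year as
dormant seeds. `bethedgr` predicts the evolutionarily stable value of `g`
for a species from its demographic responses to precipitation, and then
asks which life-history traits shape that prediction.

The resident seed bank follows a density-dependent stochastic recursion.
With `n_t` seeds per m^2 in year `t`, a fraction `g` germinates, each
germinant produces `K_t` seeds at low density, competition among the
`g n_t` seedlings discounts that yield by `1 / (1 + a g n_t)`, fresh seeds
survive to the next autumn with probability `s_new`, and dormant seeds
survive with probability `s_old`:

    n_{t+1} = g K_t s_new n_t / (1 + a g n_t)  +  (1 - g) s_old n_t.

The environmental driver is the low-density yield `K_t`, which is tied to
the year's precipitation `P_t` by a two-stage hurdle model:

* a **binomial stage**: a germinant clears the reproductive hurdle with
  probability `plogis(alpha1 + beta1 * log(P_t + 1))`;
* a **yield stage**: conditional on success,
  `log K_t = log_alpha2 + beta2 * log(P_t + 1)` (optionally plus a normal
  residual); on failure `K_t = 0.5` exactly, the offset-scale value of a
  zero-yield year.

The `+1` offset on precipitation and `+0.5` offset on yield are the
transformations under which the log-log regressions of the source
demographic data are approximately normal; both logs are natural logs. A
failure year is defined by `K_t < 1` and a success year by `K_t >= 1`
(ties count as success). Observed (competition-discounted) yields relate
to low-density yields by `Y_t = K_t / (1 + a N_t)` with `N_t = g n_t`
seedlings per m^2.

When the low-density growth rate `r = E[log(g K_t s_new + (1-g) s_old)]`
is positive the resident density converges to a unique stationary
distribution, which the package approximates by one long run
(`estimate_stationary()`); when `r <= 0` the resident goes extinct and
`estimate_stationary()` refuses to pretend otherwise.

## Invasion analysis and the ESS

A rare mutant with germination fraction `g~` invading a resident at
stationarity grows at

    r(g, g~) = E[ log( g~ K_t s_new / (1 + a g n_t) + (1 - g~) s_old ) ],

with each year's `K_t` paired with that year's pre-update resident
density `n_t`. (The mutant recursion can be written with either year's
yield index; this pairing is the only one consistent with the stationary
expectation above, and is used for resident and mutant alike.)

The selection gradient is the derivative in the mutant trait at the
resident value, computed analytically by differentiating under the
expectation:

    h(g) = E[ (Q_t - s_old) / (g Q_t + (1 - g) s_old) ],
    Q_t  = K_t s_new / (1 + a g n_t).

Because `r(g, g~)` is strictly concave in `g~`, an interior root of `h`
is the unique ESS. `find_ess()` locates it by bisection rather than
Newton steps: `h` is Monte-Carlo noisy, and bracketing a sign change is
robust where derivative-based steps are not. A 21-point pre-scan of
`h`'s sign on (0, 1) brackets the root; bisection then narrows it to a
tolerance of `1e-3` in `g` (both configurable). Common random numbers
make this reliable: one precipitation/yield stream is drawn per species
and reused for every candidate `g`, with the resident re-equilibrated at
each candidate, so `h(g)` is a smooth decreasing function of `g` along
the search rather than a noisy one.

Boundary outcomes are reported, not fudged. If `h > 0` across all of
(0, 1] — as happens in any constant environment, where at equilibrium
`h(g) = (1 - s_old)/g > 0` — the ESS is full germination and `g_ess = 1`
is returned exactly with `boundary_flag = "g_equals_1"`. If no `g`
persists, `g_ess` is `NA` with `boundary_flag = "nonpersistent"`: an
extinct resident has no germination strategy, and for such candidate
residents during a search the gradient is evaluated against a zero
resident density. `verify_ess()` closes the loop by re-equilibrating the
resident at the solved `g_ess` and checking that no mutant on a grid of
germination fractions achieves an invasion growth rate more than three
standard errors above zero.

## Fitting the hurdle from data

`fit_hurdle()` derives low-density yields from an observation table
(`observed_to_low_density_yield()`), classifies success/failure years by
the `K >= 1` rule, and fits the binomial stage by maximum-likelihood
logistic regression (`stats::glm`, i.e. iteratively reweighted least
squares with an iteration cap) and the yield stage by OLS (`stats::lm`).
Three model forms mirror the usual multi-species comparisons: `full`
(per-species intercepts and slopes), `common_slope`, and
`common_intercept`; `compare_submodels()` ranks them by AIC/BIC/log-
likelihood with likelihood-ratio tests against the full model, and
`pairwise_wald()` tests species pairs of intercepts or slopes using the
full coefficient covariance. Complete separation (a species with all
successes or all failures) is flagged with a warning when a fitted
logistic coefficient exceeds 15 in magnitude; refitting from such data is
a caller decision — the packaged coefficient table remains available when
refitting is impossible.

One convention deserves care. In raw field records a reproductive-failure
year has observed yield 0, and the `+0.5` offset is applied during
analysis; `observed_to_low_density_yield()` therefore defaults to
`K = (Y + 0.5)(1 + a N)`. Tables written by `generate_observations()`
instead record offset-scale yields (a failure year records
`0.5 / (1 + a N_t)`), and setting `offset_applied = TRUE` inverts them
exactly, `K = Y (1 + a N)`. Mixing the two conventions silently would
misclassify every generated failure year as a success (since
`0.5(2 + aN) >= 1`), which is why the flag is explicit.

## Precipitation models and calibration

Annual totals are treated as i.i.d. across years (yearly environments
exchangeable; no autocorrelation). Three `precip_model()` kinds cover the
practical cases: parametric lognormal draws, i.i.d. resampling of an
empirical series, and cycling a fixed series.
`calibrate_precip_model()` fits the lognormal by log-moment matching.
The generic default (`meanlog = log(60)`, `sdlog = 0.6`) is simply a
right-skewed desert-like series for synthetic experiments.

For the ten packaged species the scale of the driver matters and is not
recorded with the coefficients, so `sonoran_precip_model()` pins it down
from two constraints. First, the `+1` offset inside `log(P + 1)` is only
meaningful when typical totals are order 1-10 units, which rules out
millimetres. Second, all ten species must have positive stochastic growth
at their solved strategies — these populations have persisted for decades
in the field — and that holds at a median of 10 units but fails for four
species at a median of 4. Together these identify centimetres: the
calibrated model is lognormal with `meanlog = log(10)` and `sdlog = 0.5`,
i.e. a median of 10 cm (~100 mm) of germination-season rain with CV about
0.53, consistent with Sonoran Desert winter climatology. The ESS runs for
the packaged species use the deterministic (precipitation-only) hurdle,
`residual_sd = 0`, matching the two-branch yield model above; a fitted
lognormal residual can be switched on via `residual_sd`.

## What the synthetic generator does and does not emulate

`generate_observations()` produces species-year tables with exactly the
statistical structure the fitting stages assume: hurdle-drawn yields,
seed-bank density dependence, and competition-discounted observed yields.
`generate_community()` samples species uniformly within per-parameter
ranges spanning the packaged table, and
`generate_observed_fractions()` perturbs predicted ESS values on the
logit scale to mimic field germination fractions that correlate with, but
do not equal, predictions.

Passing tests on these data show the pipeline is internally consistent
and recovers what it assumes; they cannot show that real desert-annual
data satisfy those assumptions. In particular the generator omits
temperature effects, seed predation, disease, interspecific competition,
interannual autocorrelation, and observation error in densities — all
absent from the model itself as well. And a lognormal surrogate is not
the historical Tucson record: quantities conditioned on that specific
30-year realization (the published regression coefficients and adjusted
R^2 values) are only approximated under a surrogate. The package's own
long-run regression reproduces the reported structure — positive weight
on the reproductive intercept, negative on the log-yield slope, negative
and largest in magnitude on dormant-seed survival — with an adjusted R^2
around 0.75-0.86 across seeds, but the dormant-survival coefficient comes
out nearer -0.7..-0.8 than the reported -0.56.

## Trait regressions

`fit_trait_regression()` regresses `logit(g)` on standardized predictors
(sample n-1 standard deviation; the scale-free coefficients are
comparable across traits). The canonical predictor set is `alpha1`
(reproductive success in dry years), `beta2` (yield responsiveness to wet
years) and `s_old` (dormant-seed survival) — the reduction of the seven
parameters used throughout the source analysis — while any other column
set can be passed explicitly. `ess_vs_observed_fit()` performs the
simple logit-logit regression of observed germination fractions on
predicted ESS values and counts overestimated species. Responses must lie
strictly inside (0, 1); boundary ESS values (`g = 1`) have no finite
logit and are excluded by the pipeline with a warning, which is one more
reason boundary flags are explicit.

## Numerical choices and problem sizes

* Stationary runs default to 1000 burn-in years plus 50 000 retained
  years, started at 100 seeds/m^2; results are insensitive to the start
  (tested). The replicated simulations in the test suite use shorter runs
  (300-500 burn-in, 8000-20 000 years), sizes at which the Monte-Carlo
  error of `g_ess` is well below the effects being tested.
* All randomness flows from one explicit integer seed; per-species
  sub-seeds are derived by offsetting. Identical configuration and seed
  give bit-identical CSV/JSON outputs.
* Standard errors of time-averages use the naive i.i.d. formula. The
  yield stream is i.i.d. but the density sequence is autocorrelated, so
  these slightly understate the error of density-dependent averages;
  diagnostics that depend on them (stationarity z-scores, invasion
  flags) use a 3-standard-error margin.
* The seed-bank recursion itself is a compiled scalar loop; everything
  around it is vectorized R.
* Bisection reports the bracket midpoint once the bracket is narrower
  than `tol`; the gradient and resident diagnostics are re-evaluated at
  the returned `g_ess` on the same stream.

## Known limitations

* An interior ESS is assumed unique on the strength of the concavity of
  the invasion growth rate in the mutant trait; the 21-point pre-scan
  would reveal (and the uniqueness argument rules out) multiple sign
  changes.
* The i.i.d. environment ignores any wet/dry-year persistence; with
  autocorrelated rainfall the stationary density and hence the ESS would
  differ.
* Wald and profile-likelihood intervals for the binomial stage are
  asymptotic; at 30 observations per species their coverage is near but
  not exactly nominal (the test suite checks it stays within 90-99%).
* The trait regression has 10 species and 3 predictors; its coefficients
  are stable in sign and ordering but individually carry wide standard
  errors.
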