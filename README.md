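# bethedgr

Bet-hedging germination strategies for desert annual plants: predict the
evolutionarily stable fraction of a seed bank that should germinate each
year from a species' demographic responses to precipitation, and relate
those predictions to life-history traits.

Delayed germination is the classic bet-hedging strategy: in an
unpredictable desert, a species that keeps part of its seed bank dormant
sacrifices mean reproductive success to avoid losing everything in a
catastrophic dry year. `bethedgr` implements a full analysis pipeline for
this problem, built around ten common Sonoran Desert winter annuals whose
demographic parameters ship with the package:

1. **Hurdle model** — per-germinant yield as a two-stage function of
   precipitation `P`: a germinant reproduces with probability
   `plogis(α₁ + β₁ log(P + 1))`, and conditional on success produces
   `exp(log α₂ + β₂ log(P + 1))` seeds (reproductive failure is the
   offset-scale yield 0.5). Fitting, sub-model comparison
   (full / common-slope / common-intercept), likelihood-ratio and
   pairwise Wald tests are included.
2. **Seed-bank model** — the density-dependent stochastic recursion
   `n' = g K s_new n / (1 + a g n) + (1 − g) s_old n`, its low-density
   growth rate `r = E[log(g K s_new + (1 − g) s_old)]`, and long-run
   stationary distributions.
3. **ESS solver** — the invasion growth rate of a rare mutant strategy
   `g̃` against a resident `g` at stationarity,
   `r(g, g̃) = E[log(g̃ K s_new / (1 + a g n̂) + (1 − g̃) s_old)]`, its
   selection gradient `h(g) = ∂r/∂g̃ |_{g̃=g}`, and bisection for the
   evolutionarily stable germination fraction with common random
   numbers, plus an uninvadability verifier.
4. **Trait regressions** — standardized logit-scale regressions of
   germination fractions on dry-year reproductive success (`α₁`),
   wet-year yield responsiveness (`β₂`) and dormant-seed survival
   (`s_old`).
5. **Synthetic data** — lognormal/empirical/fixed precipitation models,
   observation-table and whole-community generators, so every stage is
   testable without external data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, and `autoplot()` methods for the
main result types.

## Worked example

Solve the ESS germination fraction for *Eriophyllum lanosum* (ERLA) under
the calibrated precipitation model, and verify that no mutant strategy
can invade it:

```r
library(bethedgr)

erla <- dplyr::filter(desert_annuals(), species_code == "ERLA")
res <- find_ess(erla, sonoran_precip_model(), seed = 1)
res
#> <ess_result> g_ess = 0.8569 (interior), h(g_ess) = 0.000767 +/- 0.007
#>   resident realized growth 4.67e-05 (se 0.0051); 29 gradient evaluations, tol 0.001

prof <- verify_ess(res)
max(prof$r[abs(prof$mutant_g - res$g_ess) > res$tol])
#> [1] -1.512204e-05
```

The solved strategy germinates ~86% of the seed bank each year. The two
diagnostics say the answer is internally consistent: the resident's
realized growth rate at stationarity is zero to within Monte-Carlo error
(a population at its stationary distribution neither grows nor shrinks),
and every alternative germination fraction on a 21-point grid has a
negative invasion growth rate — nothing can invade the ESS.

Running all ten species and regressing the logit ESS on standardized
traits:

```r
ess <- find_ess_all(desert_annuals(), sonoran_precip_model(), seed = 1)
traits <- dplyr::inner_join(
  desert_annuals(),
  dplyr::select(ess, species_code, g_ess, boundary_flag),
  by = "species_code"
)
fit_trait_regression(traits)
#> <trait_regression> logit(g_ess) ~ alpha1 + beta2 + s_old (standardized), n = 10
#>   coefficients: (Intercept) = 2.03, alpha1 = 0.163, beta2 = -0.603, s_old = -0.807
#>   adjusted R-squared: 0.762
```

The coefficient pattern is the scientific result: species with safer seed
banks (high `s_old`) and species that capitalize strongly on wet years
(high `β₂`) should hedge more (germinate less), while species that
reproduce reliably even in dry years (high `α₁`) should hedge less.
Dormant-seed survival carries the largest standardized weight.

`run_pipeline()` ties the stages together behind a single validated
config (list or YAML) and writes `ess.csv`, `regression_result.json` and
a manifest; see the methods vignette (`vignettes/bet-hedging-ess.Rmd`)
for the model's assumptions, calibration reasoning and numerical choices.

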