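#' One year of the seed-bank recursion
#'
#' Advances the resident seed density one year:
#' `n' = g K s_new n / (1 + a g n) + (1 - g) s_old n`.
#' A fraction `g` of seeds germinates and yields `K` seeds per germinant at
#' low density, discounted by intraspecific competition among the `g n`
#' seedlings; fresh seeds survive to the next autumn with probability
#' `s_new`. The dormant fraction `1 - g` survives with probability `s_old`.
#'
#' @param n seed density (seeds per m^2), `>= 0`; vectorized.
#' @param g germination fraction in `[0, 1]`.
#' @param K low-density yield (seeds per germinant), `> 0`; vectorized.
#' @param params a single species (row of [desert_annuals()]) supplying
#'   `s_new`, `s_old`, `a`.
#' @return next-year seed density, `0` iff `n = 0`.
#' @export
#' @examples
#' sp <- list(s_new = 0.15, s_old = 0.5, a = 0.01)
#' step_seedbank(100, g = 0.5, K = 10, params = sp)  # 75
step_seedbank <- function(n, g, K, params) {
  p <- as_species_coefs(params, c("s_new", "s_old", "a"))
  if (any(n < 0)) abort("seed density must be non-negative")
  if (g < 0 || g > 1) abort("germination fraction must lie in [0, 1]")
  if (any(K <= 0)) abort("low-density yield must be positive")
  g * K * p$s_new * n / (1 + p$a * g * n) + (1 - g) * p$s_old * n
}

# internal: full path for a yield sequence (delegates to C++)
seedbank_path <- function(n0, g, K, params) {
  p <- as_species_coefs(params, c("s_new", "s_old", "a"))
  seedbank_path_cpp(n0, g, as.numeric(K), p$s_new, p$s_old, p$a)
}

#' Simulate the stochastic seed bank
#'
#' Iterates the seed-bank recursion with yearly low-density yields drawn
#' from the hurdle model at precipitation totals produced by `precip_model`.
#' Within a year, the yield `K_t` multiplies the density `n_t` already
#' present that year.
#'
#' @param params a single species (one row of [desert_annuals()]).
#' @param g germination fraction in `[0, 1]`.
#' @param precip_model a [precip_model()], numeric series, or
#'   `(year, precip)` data frame.
#' @param years number of simulated years (`>= 1`).
#' @param n0 initial seed density (default 100 seeds per m^2).
#' @param residual_sd lognormal residual sd on success-year yields
#'   (default 0: precipitation-only variation).
#' @param seed optional integer seed.
#' @return a tibble of class `seedbank_run` with columns `year`, `precip`,
#'   `K`, `n` (density at the start of the year, i.e. paired with that
#'   year's `K`), and attributes `g`, `params`, `n_final`.
#' @export
simulate_seedbank <- function(params, g, precip_model, years,
                              n0 = 100, residual_sd = 0, seed = NULL) {
  if (!is.numeric(years) || years < 1) abort("years must be >= 1")
  if (n0 <= 0) abort("n0 must be positive")
  years <- as.integer(years)
  run <- function() {
    precip <- draw_precip(precip_model, years)
    K <- sample_low_density_yield(params, precip, residual_sd = residual_sd)
    path <- seedbank_path(n0, g, K, params)
    tibble::tibble(year = seq_len(years), precip = precip, K = K,
                   n = path[seq_len(years)], n_next = path[-1])
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, g = g, params = as_species_coefs(
    params, c("s_new", "s_old", "a")), seed = seed,
    class = c("seedbank_run", class(out)))
}

#' Low-density stochastic growth rate
#'
#' The long-run growth rate of a rare population with germination fraction
#' `g`: `r = E[log(g K_t s_new + (1 - g) s_old)]`, with `K_t` drawn from
#' the hurdle model. `r > 0` implies persistence (the density converges to
#' a unique positive stationary distribution); `r < 0` implies extinction.
#' Estimated by Monte Carlo unless `g = 0`, which returns `log(s_old)`
#' exactly.
#'
#' @inheritParams simulate_seedbank
#' @param years Monte-Carlo sample size (years drawn).
#' @return a list with `r`, `se` (0 for the exact `g = 0` case), and
#'   `years`.
#' @export
low_density_growth_rate <- function(params, g, precip_model, years = 10000,
                                    residual_sd = 0, seed = NULL) {
  p <- as_species_coefs(params, c("s_new", "s_old"))
  if (g < 0 || g > 1) abort("germination fraction must lie in [0, 1]")
  if (g == 0) {
    return(list(r = log(p$s_old), se = 0, years = 0L))
  }
  draw <- function() {
    precip <- draw_precip(precip_model, years)
    sample_low_density_yield(params, precip, residual_sd = residual_sd)
  }
  K <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  lg <- log(g * K * p$s_new + (1 - g) * p$s_old)
  list(r = mean(lg), se = sd(lg) / sqrt(length(lg)), years = years)
}

# growth rate from an already-drawn yield sequence (common random numbers)
growth_rate_from_K <- function(K, g, params) {
  p <- as_species_coefs(params, c("s_new", "s_old"))
  if (g == 0) return(log(p$s_old))
  mean(log(g * K * p$s_new + (1 - g) * p$s_old))
}

#' Approximate the stationary seed-density distribution
#'
#' Runs the resident seed bank for `burn_in + years` years and discards the
#' burn-in, approximating the stationary distribution of seed density by one
#' sufficiently long run. Errors if the resident's low-density growth rate
#' is not positive (the resident is then extinct and has no positive
#' stationary distribution).
#'
#' @inheritParams simulate_seedbank
#' @param burn_in years discarded before the stationary sample (default
#'   1000).
#' @param years post-burn-in years retained (default 50000).
#' @return a tibble of class `stationary_run`: columns `year`, `precip`,
#'   `K`, `n` (each year's `K` paired with that year's pre-update density),
#'   with a `summary` attribute (mean, sd, quantiles of `n`) and the
#'   resident `g`.
#' @export
estimate_stationary <- function(params, g, precip_model, burn_in = 1000,
                                years = 50000, n0 = 100, residual_sd = 0,
                                seed = NULL) {
  if (burn_in < 1 || years < 1) abort("burn_in and years must be positive")
  ldg <- low_density_growth_rate(params, g, precip_model,
                                 years = min(years, 20000),
                                 residual_sd = residual_sd, seed = seed)
  if (ldg$r <= 0) {
    abort(paste0(
      "resident with g = ", signif(g, 4), " is not persistent (r = ",
      signif(ldg$r, 4), " <= 0); treat it as extinct"
    ))
  }
  run <- simulate_seedbank(params, g, precip_model, years = burn_in + years,
                           n0 = n0, residual_sd = residual_sd, seed = seed)
  out <- run[(burn_in + 1):(burn_in + years), ]
  # tibble subsetting drops custom attributes; re-attach the run metadata
  attr(out, "g") <- attr(run, "g")
  attr(out, "params") <- attr(run, "params")
  attr(out, "seed") <- attr(run, "seed")
  attr(out, "summary") <- c(
    mean = mean(out$n), sd = sd(out$n),
    quantile(out$n, c(0.025, 0.25, 0.5, 0.75, 0.975))
  )
  attr(out, "burn_in") <- burn_in
  class(out) <- c("stationary_run", setdiff(class(out), "stationary_run"))
  out
}
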