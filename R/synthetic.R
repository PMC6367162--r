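#' Generate a synthetic observation table
#'
#' Simulates a species' seed bank under a germination fraction `g` and
#' records, per year, the precipitation, seedling density `N_t = g n_t`,
#' and the observed (competition-discounted) yield
#' `Y_t = K_t / (1 + a N_t)`, with `K_t` drawn from the hurdle model. The
#' recorded yields are on the offset (+0.5) scale of the hurdle — a
#' reproductive-failure year records `0.5 / (1 + a N_t)` — so the table
#' round-trips exactly through
#' [observed_to_low_density_yield()]`(offset_applied = TRUE)`.
#'
#' @inheritParams simulate_seedbank
#' @param species_code label to record (default taken from `params`, else
#'   `"SYN"`).
#' @return an `ObservationTable` tibble: `species_code`, `year`, `precip`,
#'   `seedling_density`, `observed_yield`.
#' @export
generate_observations <- function(params, g, precip_model, years,
                                  residual_sd = 0, n0 = 100, seed = NULL,
                                  species_code = NULL) {
  run <- simulate_seedbank(params, g, precip_model, years = years, n0 = n0,
                           residual_sd = residual_sd, seed = seed)
  p <- attr(run, "params")
  code <- species_code %||% params[["species_code"]] %||% "SYN"
  run |>
    tibble::as_tibble() |>
    dplyr::transmute(
      species_code = code,
      year = .data$year,
      precip = .data$precip,
      seedling_density = g * .data$n,
      observed_yield = .data$K / (1 + p$a * g * .data$n)
    )
}

community_ranges_default <- list(
  s_old = c(0.27, 0.83), s_new = c(0.10, 0.22),
  alpha1 = c(-3.9, -0.1), beta1 = c(1.4, 3.1),
  log_alpha2 = c(-1.7, 1.8), beta2 = c(0.79, 2.38),
  a = c(0.007, 0.054)
)

#' Generate a synthetic community of species
#'
#' Samples species-parameter rows uniformly within per-parameter ranges.
#' The default ranges span the packaged Sonoran species, so synthetic
#' communities resemble the observed spread of life histories.
#'
#' @param n_species number of species (`>= 2`).
#' @param ranges named list of `c(min, max)` ranges for each parameter;
#'   defaults span the packaged species. `min = max` pins a parameter.
#' @param seed optional integer seed.
#' @return a species-parameter tibble with codes `S01`, `S02`, ...
#' @export
generate_community <- function(n_species, ranges = list(), seed = NULL) {
  if (!is.numeric(n_species) || n_species < 2) abort("n_species must be >= 2")
  n_species <- as.integer(n_species)
  rng <- modifyList(community_ranges_default, ranges)
  unknown <- setdiff(names(rng), names(community_ranges_default))
  if (length(unknown) > 0) {
    abort(paste0("unknown parameter range(s): ", paste(unknown, collapse = ", ")))
  }
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2]) {
      abort(paste0("range for '", nm, "' must be finite c(min, max) with min <= max"))
    }
  }
  draw <- function() {
    purrr::map_dfc(rng, function(r) runif(n_species, r[1], r[2]))
  }
  tab <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- dplyr::bind_cols(
    tibble::tibble(species_code = sprintf("S%02d", seq_len(n_species))),
    tab
  )
  validate_species_params(out)
}

#' Generate observed-germination-fraction stand-ins
#'
#' Produces plausible "observed" germination fractions from predicted ESS
#' values by perturbing them on the logit scale:
#' `inv_logit(logit(g_ess) + Normal(0, sd))`. Mirrors the empirical pattern
#' that observed fractions correlate with, but do not equal, model
#' predictions.
#'
#' @param g_ess predicted ESS germination fractions strictly inside (0, 1).
#' @param sd logit-scale noise standard deviation (default 0.5).
#' @param seed optional integer seed.
#' @return a numeric vector of fractions in (0, 1).
#' @export
generate_observed_fractions <- function(g_ess, sd = 0.5, seed = NULL) {
  if (sd < 0) abort("sd must be non-negative")
  base <- logit(g_ess)
  draw <- function() inv_logit(base + rnorm(length(base), 0, sd))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
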