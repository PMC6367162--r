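#' Log-precipitation transform
#'
#' Precipitation enters every regression in the model as `log(P + 1)`; the
#' +1 offset keeps the transform defined at zero rainfall and (with the
#' yield offset) makes regression residuals approximately normal.
#'
#' @param precip numeric vector of precipitation totals, `>= 0` and finite.
#' @return `log(precip + 1)`, same length as the input.
#' @export
#' @examples
#' log_precip(c(0, exp(1) - 1, 27))
log_precip <- function(precip) {
  if (!is.numeric(precip) || any(!is.finite(precip)) || any(precip < 0)) {
    abort("precipitation must be finite and non-negative")
  }
  log(precip + 1)
}

#' Yield offset transform
#'
#' Observed yields get a +0.5 offset before any log transform; a zero-yield
#' (reproductive failure) year therefore maps to 0.5, the failure branch of
#' the hurdle model.
#'
#' @param yield numeric vector of raw yields, `>= 0`.
#' @return `yield + 0.5`.
#' @export
offset_yield <- function(yield) {
  if (!is.numeric(yield) || any(!is.finite(yield)) || any(yield < 0)) {
    abort("yield must be finite and non-negative")
  }
  yield + 0.5
}

#' Probability of reproductive success
#'
#' The binomial stage of the hurdle model: the probability that a germinant
#' clears the reproductive hurdle in a year with precipitation `precip`,
#' `plogis(alpha1 + beta1 * log(P + 1))`.
#'
#' @param params a single species: one row of [desert_annuals()] or a named
#'   list with at least `alpha1` and `beta1`.
#' @param precip precipitation total(s), `> 0`.
#' @return probabilities in (0, 1), vectorized over `precip`.
#' @export
#' @examples
#' erla <- dplyr::filter(desert_annuals(), species_code == "ERLA")
#' reproduction_probability(erla, c(1, 4, 10))
reproduction_probability <- function(params, precip) {
  p <- as_species_coefs(params, c("alpha1", "beta1"))
  stats::plogis(p$alpha1 + p$beta1 * log_precip(precip))
}

#' Expected low-density yield given reproductive success
#'
#' The continuous stage of the hurdle model: conditional on clearing the
#' hurdle, the low-density yield is
#' `exp(log_alpha2 + beta2 * log(P + 1))` seeds per germinant.
#'
#' @inheritParams reproduction_probability
#' @return positive yields, vectorized over `precip`.
#' @export
success_yield <- function(params, precip) {
  p <- as_species_coefs(params, c("log_alpha2", "beta2"))
  exp(p$log_alpha2 + p$beta2 * log_precip(precip))
}

# minimal coefficient extraction for the scalar hurdle functions
as_species_coefs <- function(params, fields) {
  if (is.data.frame(params)) {
    if (nrow(params) != 1) abort("expected a single species (one-row data frame)")
    params <- as.list(params)
  }
  missing <- setdiff(fields, names(params))
  if (length(missing) > 0) {
    abort(paste0("species parameters lack field(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (f in fields) {
    if (!is.numeric(params[[f]]) || !is.finite(params[[f]])) {
      abort(paste0("field '", f, "' must be finite numeric"))
    }
  }
  params
}

#' Draw low-density yields from the hurdle model
#'
#' Samples `K_t` for each year: with probability `pi_t` (the reproductive
#' hurdle) the success yield `alpha2 * P^beta2` — optionally times a
#' lognormal residual — and otherwise exactly 0.5, the offset-scale value of
#' a zero-yield year.
#'
#' @inheritParams reproduction_probability
#' @param residual_sd standard deviation of the log-scale residual applied
#'   to success-year yields; 0 (default) gives the deterministic
#'   precipitation-only model.
#' @param seed optional integer; when given, draws are made under this seed
#'   without disturbing the global RNG state.
#' @return numeric vector of yields, one per element of `precip`.
#' @export
sample_low_density_yield <- function(params, precip, residual_sd = 0,
                                     seed = NULL) {
  if (!is.numeric(residual_sd) || residual_sd < 0) {
    abort("residual_sd must be non-negative")
  }
  draw <- function() {
    pi_t <- reproduction_probability(params, precip)
    k <- success_yield(params, precip)
    if (residual_sd > 0) {
      # median-1 multiplicative residual: log K keeps mean log_alpha2 + beta2 x,
      # so refitting the log-linear stage recovers the generating coefficients
      k <- k * exp(rnorm(length(k), 0, residual_sd))
    }
    ifelse(runif(length(pi_t)) < pi_t, k, 0.5)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Convert observed yields to low-density yields
#'
#' Inverts the competition correction `Y_t = K_t / (1 + a N_t)` on an
#' observation table, recovering the low-density yield `K_t` of each year,
#' and classifies years as reproductive successes (`K >= 1`) or failures
#' (`K < 1`).
#'
#' @param data observation table with columns `species_code`, `precip`,
#'   `seedling_density`, `observed_yield` (and typically `year`).
#' @param params species-parameter table supplying the competition
#'   coefficient `a` per `species_code`.
#' @param offset_applied do the recorded yields already carry the +0.5
#'   offset convention (as tables written by [generate_observations()] do)?
#'   If `FALSE` (the default, appropriate for raw field data where failure
#'   years record 0), the +0.5 offset is added to the observed yield before
#'   inverting the competition factor.
#' @return the input tibble with columns `log_precip`, `K` and logical
#'   `success` appended.
#' @export
observed_to_low_density_yield <- function(data, params,
                                          offset_applied = FALSE) {
  for (col in c("species_code", "precip", "seedling_density", "observed_yield")) {
    if (!col %in% names(data)) abort(paste0("observation table lacks column '", col, "'"))
  }
  if (any(data$observed_yield < 0)) abort("observed_yield must be non-negative")
  if (any(data$seedling_density < 0)) abort("seedling_density must be non-negative")
  validate_species_params(params)
  data |>
    tibble::as_tibble() |>
    dplyr::left_join(dplyr::select(params, "species_code", "a"),
                     by = "species_code") |>
    dplyr::mutate(
      log_precip = log_precip(.data$precip),
      K = (if (offset_applied) .data$observed_yield
           else offset_yield(.data$observed_yield)) *
        (1 + .data$a * .data$seedling_density),
      success = .data$K >= 1
    ) |>
    dplyr::select(-"a")
}
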