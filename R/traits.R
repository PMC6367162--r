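#' Logit and inverse-logit transforms
#'
#' Germination fractions are analysed on the log-odds scale:
#' `logit(p) = log(p / (1 - p))`, with `inv_logit` its inverse.
#'
#' @param p probabilities strictly inside (0, 1).
#' @param x real log-odds values.
#' @return numeric vector of the same length.
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("logit requires values strictly inside (0, 1)")
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Standardize a predictor to z-scores
#'
#' Centers and scales with the sample (n-1) standard deviation, so
#' standardized regression coefficients are comparable across predictors
#' measured in different units.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return z-scores with mean 0 and sample sd 1.
#' @export
standardize <- function(x) {
  if (length(x) < 2 || any(!is.finite(x))) {
    abort("need >= 2 finite values to standardize")
  }
  s <- sd(x)
  if (s == 0) abort("cannot standardize a zero-variance predictor")
  (x - mean(x)) / s
}

trait_predictors_default <- c("alpha1", "beta2", "s_old")

#' Regress germination fractions on standardized life-history traits
#'
#' Fits, by ordinary least squares, the logit of a germination fraction
#' (model-predicted ESS or observed) on standardized life-history
#' predictors. The canonical predictor set is the reproductive intercept
#' (`alpha1`, success in dry years), the log-yield slope (`beta2`,
#' responsiveness to wet years) and dormant-seed survival (`s_old`); the
#' full seven-parameter set can be requested instead via `predictors`.
#'
#' @param data a tibble with one row per species containing the predictor
#'   columns and the response column.
#' @param response name of the response column, a germination fraction
#'   strictly inside (0, 1) (default `"g_ess"`).
#' @param predictors character vector of predictor column names (default
#'   `c("alpha1", "beta2", "s_old")`).
#' @return an object of class `trait_regression` wrapping the [stats::lm()]
#'   fit on standardized predictors; see [tidy.trait_regression()] and
#'   [glance.trait_regression()].
#' @export
fit_trait_regression <- function(data, response = "g_ess",
                                 predictors = trait_predictors_default) {
  if (!is.data.frame(data)) abort("data must be a data frame")
  for (col in c(predictors, response)) {
    if (!col %in% names(data)) abort(paste0("data lacks column '", col, "'"))
  }
  n <- nrow(data)
  if (n < length(predictors) + 2) {
    abort(paste0("need at least ", length(predictors) + 2,
                 " species to fit ", length(predictors), " predictors"))
  }
  y <- logit(data[[response]])
  X <- purrr::map_dfc(setNames(predictors, predictors),
                      function(col) standardize(data[[col]]))
  df <- dplyr::bind_cols(tibble::tibble(.logit_response = y), X)
  fit <- lm(as.formula(paste(".logit_response ~",
                             paste(predictors, collapse = " + "))),
            data = df)
  if (fit$rank < length(predictors) + 1) {
    warn("collinear predictors: trait regression is rank deficient")
  }
  structure(
    list(fit = fit, response = response, predictors = predictors, n = n,
         species_code = data[["species_code"]] %||% as.character(seq_len(n))),
    class = "trait_regression"
  )
}

#' @export
print.trait_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  cat("<trait_regression> logit(", x$response, ") ~ ",
      paste(x$predictors, collapse = " + "),
      " (standardized), n = ", x$n, "\n", sep = "")
  cat("  coefficients:",
      paste(sprintf("%s = %.3g", names(coef(x$fit)), coef(x$fit)),
            collapse = ", "), "\n")
  cat("  adjusted R-squared:", signif(s$adj.r.squared, 4), "\n")
  invisible(x)
}

#' Tidy a trait regression
#'
#' @param x a `trait_regression` or `ess_obs_fit`.
#' @param ... unused.
#' @return a tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (terms other than the intercept are standardized
#'   coefficients).
#' @export
tidy.trait_regression <- function(x, ...) {
  # suppress the "essentially perfect fit" chatter on noiseless inputs
  co <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = rownames(co), estimate = co[, 1], std.error = co[, 2],
    statistic = co[, 3], p.value = co[, 4]
  )
}

#' Fit summary of a trait regression
#'
#' @param x a `trait_regression` or `ess_obs_fit`.
#' @param ... unused.
#' @return a one-row tibble with `r.squared`, `adj.r.squared`, `sigma`,
#'   `n`, `p` (number of predictors).
#' @export
glance.trait_regression <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma, n = x$n, p = length(x$predictors)
  )
}

#' Regress observed germination fractions on predicted ESS values
#'
#' Simple OLS of `logit(observed)` on `logit(predicted)` — how much of the
#' variation in realized germination fractions the ESS predictions explain
#' — plus an overestimation diagnostic (how many species the model predicts
#' to germinate more than observed).
#'
#' @param data a tibble with one row per species.
#' @param predicted,observed names of the columns holding predicted ESS and
#'   observed germination fractions, both strictly inside (0, 1).
#' @return an object of classes `ess_obs_fit` and `trait_regression`; its
#'   [glance()] additionally reports `slope`, `intercept` and
#'   `n_overestimated`.
#' @export
ess_vs_observed_fit <- function(data, predicted = "g_ess",
                                observed = "g_obs") {
  for (col in c(predicted, observed)) {
    if (!col %in% names(data)) abort(paste0("data lacks column '", col, "'"))
  }
  lp <- logit(data[[predicted]])
  lo <- logit(data[[observed]])
  fit <- lm(lo ~ lp)
  out <- structure(
    list(fit = fit, response = observed, predictors = predicted,
         n = nrow(data),
         n_overestimated = sum(data[[predicted]] > data[[observed]]),
         species_code = data[["species_code"]] %||%
           as.character(seq_len(nrow(data)))),
    class = c("ess_obs_fit", "trait_regression")
  )
  out
}

#' @export
glance.ess_obs_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    slope = coef(x$fit)[[2]], intercept = coef(x$fit)[[1]],
    n = x$n, n_overestimated = x$n_overestimated
  )
}
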