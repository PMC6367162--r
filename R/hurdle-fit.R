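#' Fit the binomial (reproductive-hurdle) stage
#'
#' Logistic regression of reproductive success/failure on log-precipitation.
#' Three model forms are supported: `"full"` fits a separate intercept and
#' slope per species, `"common_slope"` shares one slope across species, and
#' `"common_intercept"` shares one intercept. With a single species the
#' three forms coincide.
#'
#' @param data tibble with columns `species_code`, `log_precip`, and logical
#'   (or 0/1) `success` — one row per species-year, as produced by
#'   [observed_to_low_density_yield()].
#' @param model_form one of `"full"`, `"common_slope"`, `"common_intercept"`.
#' @return an object of class `hurdle_stage_fit` wrapping the fitted
#'   [stats::glm()]; see [tidy.hurdle_stage_fit()] and
#'   [glance.hurdle_stage_fit()].
#' @export
fit_binomial_stage <- function(data,
                               model_form = c("full", "common_slope",
                                              "common_intercept")) {
  model_form <- match.arg(model_form)
  data <- check_stage_data(data, response = "success")
  if (all(data$success == 0) || all(data$success == 1)) {
    abort("need at least one reproductive success and one failure to fit the hurdle")
  }
  f <- stage_formula("success", model_form, n_species = dplyr::n_distinct(data$species_code))
  fit <- withCallingHandlers(
    glm(f, family = binomial(), data = data, control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warn("possible complete separation in the binomial stage; coefficients may diverge")
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(abs(coef(fit)) > 15, na.rm = TRUE)) {
    warn(paste0(
      "diverging binomial coefficient(s) (|estimate| > 15): ",
      paste(names(coef(fit))[abs(coef(fit)) > 15], collapse = ", "),
      "; a species may have all successes or all failures"
    ))
  }
  new_stage_fit(fit, stage = "binomial", model_form = model_form, data = data)
}

#' Fit the log-linear (post-hurdle yield) stage
#'
#' Ordinary least squares of log low-density yield on log-precipitation,
#' restricted to reproductive-success years (`K >= 1`). Model forms as in
#' [fit_binomial_stage()].
#'
#' @param data tibble with columns `species_code`, `log_precip`, `log_K`
#'   (success years only).
#' @inheritParams fit_binomial_stage
#' @return an object of class `hurdle_stage_fit` wrapping the fitted
#'   [stats::lm()].
#' @export
fit_yield_stage <- function(data,
                            model_form = c("full", "common_slope",
                                           "common_intercept")) {
  model_form <- match.arg(model_form)
  data <- check_stage_data(data, response = "log_K")
  f <- stage_formula("log_K", model_form, n_species = dplyr::n_distinct(data$species_code))
  fit <- lm(f, data = data)
  if (anyNA(coef(fit))) {
    abort("rank-deficient yield stage: a fitted line has fewer than 2 distinct log-precipitation values")
  }
  new_stage_fit(fit, stage = "yield", model_form = model_form, data = data)
}

check_stage_data <- function(data, response) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("stage data must be a non-empty data frame")
  }
  for (col in c("species_code", "log_precip", response)) {
    if (!col %in% names(data)) abort(paste0("stage data lacks column '", col, "'"))
  }
  data <- tibble::as_tibble(data)
  data$species_code <- factor(data$species_code)
  if (response == "success") data$success <- as.numeric(data$success)
  counts <- table(data$species_code)
  if (any(counts < 2)) {
    abort(paste0("need >= 2 observations per species; too few for ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  data
}

stage_formula <- function(response, model_form, n_species) {
  rhs <- if (n_species == 1) {
    "log_precip"
  } else {
    switch(model_form,
      full             = "0 + species_code + species_code:log_precip",
      common_slope     = "0 + species_code + log_precip",
      common_intercept = "species_code:log_precip"
    )
  }
  as.formula(paste(response, "~", rhs))
}

new_stage_fit <- function(fit, stage, model_form, data) {
  structure(
    list(
      fit = fit,
      stage = stage,
      model_form = model_form,
      species = levels(data$species_code),
      n = nrow(data),
      fingerprint = c(nrow(data), sum(data$log_precip),
                      sum(data[[if (stage == "binomial") "success" else "log_K"]]))
    ),
    class = "hurdle_stage_fit"
  )
}

#' @export
print.hurdle_stage_fit <- function(x, ...) {
  cat("<hurdle_stage_fit> ", x$stage, " stage, model form '", x$model_form,
      "', ", length(x$species), " species, n = ", x$n, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy a hurdle stage fit
#'
#' One row per species and coefficient role (`intercept`, `slope`), with the
#' estimate, standard error and whether the coefficient is shared across
#' species under the fitted model form.
#'
#' @param x a `hurdle_stage_fit`.
#' @param ... unused.
#' @return a tibble with columns `species_code`, `term`, `estimate`,
#'   `std.error`, `shared`.
#' @export
tidy.hurdle_stage_fit <- function(x, ...) {
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  map <- coef_map(x)
  purrr::pmap_dfr(map, function(species_code, term, name, shared) {
    tibble::tibble(species_code = species_code, term = term,
                   estimate = unname(b[name]), std.error = unname(se[name]),
                   shared = shared)
  })
}

# which fitted coefficient serves as intercept / slope for each species
coef_map <- function(x) {
  sp <- x$species
  if (length(sp) == 1) {
    return(tibble::tibble(
      species_code = sp, term = c("intercept", "slope"),
      name = c("(Intercept)", "log_precip"), shared = FALSE
    ))
  }
  int_names <- switch(x$model_form,
    full             = paste0("species_code", sp),
    common_slope     = paste0("species_code", sp),
    common_intercept = rep("(Intercept)", length(sp))
  )
  slope_names <- switch(x$model_form,
    full             = paste0("species_code", sp, ":log_precip"),
    common_slope     = rep("log_precip", length(sp)),
    common_intercept = paste0("species_code", sp, ":log_precip")
  )
  tibble::tibble(
    species_code = rep(sp, 2),
    term = rep(c("intercept", "slope"), each = length(sp)),
    name = c(int_names, slope_names),
    shared = c(rep(x$model_form == "common_intercept", length(sp)),
               rep(x$model_form == "common_slope", length(sp)))
  )
}

#' Fit statistics of a hurdle stage fit
#'
#' @param x a `hurdle_stage_fit`.
#' @param ... unused.
#' @return a one-row tibble with `stage`, `model_form`, `k` (estimated
#'   parameters, counting the residual variance for the yield stage),
#'   `loglik`, `aic`, `bic`, `n`, and `residual_sd` (NA for the binomial
#'   stage).
#' @export
glance.hurdle_stage_fit <- function(x, ...) {
  ll <- logLik(x$fit)
  tibble::tibble(
    stage = x$stage,
    model_form = x$model_form,
    k = attr(ll, "df"),
    loglik = as.numeric(ll),
    aic = AIC(x$fit),
    bic = BIC(x$fit),
    n = x$n,
    residual_sd = if (x$stage == "yield") stats::sigma(x$fit) else NA_real_
  )
}

#' Fit both stages of the hurdle model
#'
#' Derives low-density yields from an observation table, classifies
#' success/failure years, and fits the binomial and log-linear stages.
#'
#' @inheritParams observed_to_low_density_yield
#' @inheritParams fit_binomial_stage
#' @return an object of class `hurdle_fit`: a list with elements `binomial`
#'   and `yield` (each a `hurdle_stage_fit`) plus the derived data.
#' @export
fit_hurdle <- function(data, params,
                       model_form = c("full", "common_slope",
                                      "common_intercept"),
                       offset_applied = FALSE) {
  model_form <- match.arg(model_form)
  derived <- observed_to_low_density_yield(data, params,
                                           offset_applied = offset_applied)
  yield_data <- derived |>
    dplyr::filter(.data$success) |>
    dplyr::mutate(log_K = log(.data$K))
  structure(
    list(
      binomial = fit_binomial_stage(derived, model_form),
      yield = fit_yield_stage(yield_data, model_form),
      model_form = model_form,
      data = derived
    ),
    class = "hurdle_fit"
  )
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("<hurdle_fit> model form '", x$model_form, "', ",
      length(x$binomial$species), " species\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.hurdle_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$binomial), stage = "binomial", .before = 1),
    dplyr::mutate(tidy(x$yield), stage = "yield", .before = 1)
  )
}

#' @export
glance.hurdle_fit <- function(x, ...) {
  dplyr::bind_rows(glance(x$binomial), glance(x$yield))
}

#' Extract a species-parameter table from a fitted hurdle model
#'
#' Reshapes a full-model [fit_hurdle()] into per-species hurdle coefficients
#' (`alpha1`, `beta1`, `log_alpha2`, `beta2`) plus the yield stage's residual
#' standard deviation, ready to join with survival and competition data and
#' feed the ESS pipeline.
#'
#' @param fit a `hurdle_fit`.
#' @return a tibble, one row per species.
#' @export
hurdle_coef_table <- function(fit) {
  stopifnot(inherits(fit, "hurdle_fit"))
  wide <- function(stage_fit, names_to) {
    tidy(stage_fit) |>
      dplyr::select("species_code", "term", "estimate") |>
      tidyr::pivot_wider(names_from = "term", values_from = "estimate") |>
      dplyr::rename_with(~ names_to, c("intercept", "slope"))
  }
  dplyr::left_join(
    wide(fit$binomial, c("alpha1", "beta1")),
    wide(fit$yield, c("log_alpha2", "beta2")),
    by = "species_code"
  ) |>
    dplyr::mutate(residual_sd = stats::sigma(fit$yield$fit))
}

#' Compare nested hurdle sub-models
#'
#' Ranks a set of stage fits (on identical data) by AIC/BIC/log-likelihood
#' and reports likelihood-ratio tests of each sub-model against the full
#' model, when a full model is among them.
#'
#' @param ... `hurdle_stage_fit` objects, or a single list of them.
#' @return a tibble with one row per fit: `model_form`, `k`, `loglik`,
#'   `aic`, `bic`, and (against the full model) `lr_stat`, `lr_df`,
#'   `lr_p_value`.
#' @export
compare_submodels <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && !inherits(fits[[1]], "hurdle_stage_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "hurdle_stage_fit")))
  fp <- vapply(fits, function(f) f$fingerprint, numeric(3))
  if (any(abs(fp - fp[, 1]) > 1e-8)) {
    abort("sub-models were not fitted on identical data")
  }
  tab <- purrr::map_dfr(fits, glance)
  full_idx <- which(tab$model_form == "full")
  if (length(full_idx) >= 1) {
    full <- tab[full_idx[1], ]
    tab <- tab |>
      dplyr::mutate(
        lr_stat = 2 * (full$loglik - .data$loglik),
        lr_df = full$k - .data$k,
        lr_p_value = ifelse(.data$lr_df > 0,
                            pchisq(.data$lr_stat, .data$lr_df, lower.tail = FALSE),
                            NA_real_)
      )
  }
  dplyr::arrange(tab, .data$aic)
}

#' Pairwise Wald tests between species-specific coefficients
#'
#' For every pair of species, tests equality of their fitted coefficients of
#' one family (intercepts or slopes) with the Wald statistic
#' `z = (b_i - b_j) / sqrt(v_ii + v_jj - 2 v_ij)` and a two-sided normal
#' p-value; a Bonferroni-adjusted column is included.
#'
#' @param x a `hurdle_stage_fit` whose model form leaves the chosen family
#'   species-specific (e.g. intercepts under `"full"` or `"common_slope"`).
#' @param family `"intercept"` or `"slope"`.
#' @return a tibble with one row per unordered species pair: `species_i`,
#'   `species_j`, `estimate_i`, `estimate_j`, `z`, `p_value`,
#'   `p_bonferroni`.
#' @export
pairwise_wald <- function(x, family = c("intercept", "slope")) {
  family <- match.arg(family)
  stopifnot(inherits(x, "hurdle_stage_fit"))
  map <- dplyr::filter(coef_map(x), .data$term == family)
  if (any(map$shared) || length(unique(map$name)) < 2) {
    abort(paste0("model form '", x$model_form,
                 "' has no species-specific ", family, "s to compare"))
  }
  b <- coef(x$fit)[map$name]
  V <- vcov(x$fit)[map$name, map$name]
  if (anyNA(V)) abort("coefficient covariance unavailable")
  pairs <- utils::combn(seq_len(nrow(map)), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    v <- V[i, i] + V[j, j] - 2 * V[i, j]
    z <- (b[[i]] - b[[j]]) / sqrt(v)
    tibble::tibble(
      species_i = map$species_code[i], species_j = map$species_code[j],
      estimate_i = b[[i]], estimate_j = b[[j]],
      z = z, p_value = 2 * pnorm(-abs(z))
    )
  })
  dplyr::mutate(out, p_bonferroni = p.adjust(.data$p_value, "bonferroni"))
}
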