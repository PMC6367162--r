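#' Read and write species-parameter tables
#'
#' CSV with declared header `species_code, s_old, s_new, alpha1, beta1,
#' log_alpha2, beta2, a`; values are validated on read (see
#' [validate_species_params()]) and written at full precision.
#'
#' @param path file path.
#' @param params a species-parameter table.
#' @return `read_species_params()` returns a validated tibble;
#'   `write_species_params()` returns `path` invisibly.
#' @export
read_species_params <- function(path) {
  tab <- read_checked_csv(path, c(species_code = "c", s_old = "d", s_new = "d",
                                  alpha1 = "d", beta1 = "d", log_alpha2 = "d",
                                  beta2 = "d", a = "d"))
  validate_species_params(tab)
}

#' @rdname read_species_params
#' @export
write_species_params <- function(params, path) {
  validate_species_params(params)
  readr::write_csv(params, path)
  invisible(path)
}

#' Read and write precipitation series
#'
#' CSV with columns `year, precip`; totals must be positive and finite.
#'
#' @param path file path.
#' @param precip a `(year, precip)` tibble.
#' @return `read_precip()` returns a tibble; `write_precip()` returns
#'   `path` invisibly.
#' @export
read_precip <- function(path) {
  tab <- read_checked_csv(path, c(year = "d", precip = "d"))
  bad <- which(!is.finite(tab$precip) | tab$precip <= 0)
  if (length(bad) > 0) {
    abort(paste0("non-positive precipitation in row ", bad[1], " of ", path))
  }
  tab
}

#' @rdname read_precip
#' @export
write_precip <- function(precip, path) {
  readr::write_csv(precip[, c("year", "precip")], path)
  invisible(path)
}

#' Read an observation table
#'
#' CSV with columns `species_code, year, precip, seedling_density,
#' observed_yield`; precipitation must be positive, densities and yields
#' non-negative.
#'
#' @param path file path.
#' @return a tibble.
#' @export
read_observations <- function(path) {
  tab <- read_checked_csv(path, c(species_code = "c", year = "d",
                                  precip = "d", seedling_density = "d",
                                  observed_yield = "d"))
  checks <- list(
    precip = function(x) is.finite(x) & x > 0,
    seedling_density = function(x) is.finite(x) & x >= 0,
    observed_yield = function(x) is.finite(x) & x >= 0
  )
  for (col in names(checks)) {
    bad <- which(!checks[[col]](tab[[col]]))
    if (length(bad) > 0) {
      abort(paste0("invalid value in column '", col, "', row ", bad[1],
                   " of ", path))
    }
  }
  tab
}

#' @rdname read_observations
#' @param observations an observation tibble.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(observations, path)
  invisible(path)
}

# strict CSV reader: declared header, declared types, named errors
read_checked_csv <- function(path, spec) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                            progress = FALSE)
  missing <- setdiff(names(spec), names(header))
  if (length(missing) > 0) {
    abort(paste0(path, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  tab <- suppressWarnings(
    readr::read_csv(path,
                    col_types = do.call(readr::cols,
                                        as.list(setNames(unname(spec), names(spec)))),
                    progress = FALSE)
  )
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(paste0("non-numeric or malformed cell in ", path, ", row ",
                 probs$row[1], ", column ", probs$col[1]))
  }
  tibble::as_tibble(tab)[, union(names(spec), names(tab))]
}

#' Serialize a fitted hurdle model to JSON
#'
#' Writes coefficients, covariance matrices, fit statistics and the model
#' form of both stages, at full precision.
#'
#' @param fit a `hurdle_fit`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_hurdle_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hurdle_fit"))
  stage_json <- function(sf) {
    list(
      model_form = sf$model_form,
      coefficients = as.list(coef(sf$fit)),
      vcov = unclass(vcov(sf$fit)),
      tidy = tidy(sf),
      glance = glance(sf)
    )
  }
  jsonlite::write_json(
    list(binomial = stage_json(fit$binomial), yield = stage_json(fit$yield)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns", matrix = "rowmajor"
  )
  invisible(path)
}

pipeline_config_default <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    species_params = NULL,
    observations = NULL,
    observed_fractions = NULL,
    model_form = "full",
    precip_model = list(kind = "lognormal", meanlog = log(10), sdlog = 0.5,
                        series = NULL, path = NULL),
    burn_in = 1000, years = 50000, n0 = 100,
    residual_sd = 0, tol = 1e-3
  )
}

#' Run the full analysis pipeline
#'
#' Ties the stages together: load (or generate) species parameters,
#' optionally refit the hurdle model from an observation table, solve the
#' ESS germination fraction for every species, regress logit ESS on the
#' standardized life-history traits, and (when observed fractions are
#' supplied) regress observed on predicted. Outputs are written as CSV/JSON
#' under `out_dir` when it is set; reruns with the same config and seed are
#' bit-identical.
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults: `seed`, `out_dir`, `species_params` (path; `NULL` uses the
#'   packaged table), `observations` (path; when given the hurdle is refit
#'   and its coefficients replace the packaged ones), `observed_fractions`
#'   (path to a `species_code, g_obs` CSV), `model_form`, `precip_model`
#'   (list with `kind`, `meanlog`, `sdlog`, `path`), `burn_in`, `years`,
#'   `n0`, `residual_sd`, `tol`. Unknown keys are rejected.
#' @param quiet suppress progress messages.
#' @return a list with elements `species`, `ess` (per-species results),
#'   `trait_fit` (`trait_regression` on interior ESS values, or `NULL` if
#'   fewer than 5), `obs_fit` (when observed fractions were supplied),
#'   `hurdle_fit` (when observations were supplied), and `config`.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_config_default()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$precip_model)) {
    bad <- setdiff(names(config$precip_model), names(defaults$precip_model))
    if (length(bad) > 0) {
      abort(paste0("unknown precip_model key(s): ", paste(bad, collapse = ", ")))
    }
  }
  cfg <- modifyList(defaults, config)
  say <- function(...) if (!quiet) message("[bethedgr] ", ...)

  species <- if (is.null(cfg$species_params)) {
    desert_annuals()
  } else {
    read_species_params(cfg$species_params)
  }
  say("species table: ", nrow(species), " species")

  pm <- cfg$precip_model
  model <- if (!is.null(pm$path)) {
    calibrate_precip_model(read_precip(pm$path))
  } else {
    precip_model(pm$kind, meanlog = pm$meanlog, sdlog = pm$sdlog,
                 series = pm$series)
  }

  hurdle <- NULL
  residual_sd <- cfg$residual_sd
  if (!is.null(cfg$observations)) {
    obs <- read_observations(cfg$observations)
    say("refitting hurdle model (", cfg$model_form, ") from ",
        nrow(obs), " observations")
    hurdle <- fit_hurdle(obs, species, model_form = cfg$model_form)
    refit <- hurdle_coef_table(hurdle)
    species <- species |>
      dplyr::select(-dplyr::all_of(c("alpha1", "beta1", "log_alpha2", "beta2"))) |>
      dplyr::inner_join(dplyr::select(refit, -"residual_sd"),
                        by = "species_code")
    if (isTRUE(cfg$residual_sd)) residual_sd <- stats::sigma(hurdle$yield$fit)
  }
  if (isTRUE(residual_sd)) {
    abort("residual_sd = TRUE requires an observation table to estimate it from")
  }

  say("solving ESS for ", nrow(species), " species (burn_in = ",
      cfg$burn_in, ", years = ", cfg$years, ")")
  ess <- find_ess_all(species, model, tol = cfg$tol, seed = cfg$seed,
                      burn_in = cfg$burn_in, years = cfg$years,
                      n0 = cfg$n0, residual_sd = residual_sd)

  traits <- species |>
    dplyr::inner_join(dplyr::select(ess, "species_code", "g_ess",
                                    "boundary_flag"),
                      by = "species_code") |>
    dplyr::filter(.data$boundary_flag == "interior")
  trait_fit <- NULL
  if (nrow(traits) >= 5) {
    say("regressing logit ESS on standardized traits (n = ", nrow(traits), ")")
    trait_fit <- fit_trait_regression(traits, response = "g_ess")
  } else {
    warn("fewer than 5 interior ESS values; skipping trait regression")
  }

  obs_fit <- NULL
  if (!is.null(cfg$observed_fractions)) {
    frac <- read_checked_csv(cfg$observed_fractions,
                             c(species_code = "c", g_obs = "d"))
    joined <- dplyr::inner_join(traits, frac, by = "species_code")
    obs_fit <- ess_vs_observed_fit(joined)
  }

  out <- list(species = species, ess = ess, trait_fit = trait_fit,
              obs_fit = obs_fit, hurdle_fit = hurdle, config = cfg)
  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(out, cfg$out_dir)
    say("outputs written to ", cfg$out_dir)
  }
  out
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- out$config
  ess_tab <- out$ess |>
    dplyr::select(-"result") |>
    dplyr::mutate(tol = cfg$tol, burn_in = cfg$burn_in, years = cfg$years,
                  seed = cfg$seed,
                  precip_model = paste0(cfg$precip_model$kind, "(",
                                        signif(cfg$precip_model$meanlog, 10), ",",
                                        signif(cfg$precip_model$sdlog, 10), ")"))
  readr::write_csv(ess_tab, file.path(dir, "ess.csv"))
  if (!is.null(out$trait_fit)) {
    jsonlite::write_json(
      list(coefficients = tidy(out$trait_fit), glance = glance(out$trait_fit)),
      file.path(dir, "regression_result.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
  }
  if (!is.null(out$hurdle_fit)) {
    write_hurdle_fit(out$hurdle_fit, file.path(dir, "hurdle_fit.json"))
  }
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
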