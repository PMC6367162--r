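#' Life-history and hurdle parameters of ten Sonoran Desert annuals
#'
#' Returns the packaged species-parameter table: one row per species with its
#' seed survival rates, hurdle-model coefficients and competition coefficient.
#' These are the field-estimated values for ten common winter annuals of the
#' Sonoran Desert (species codes MOBE, ERCI, STMI, SCBA, ERLA, PLPA, ERTE,
#' PLIN, PERE, EVMU).
#'
#' @details Columns:
#' \describe{
#'   \item{species_code}{four-letter species label.}
#'   \item{s_old}{annual survival probability of dormant seeds in the seed
#'     bank.}
#'   \item{s_new}{survival probability of freshly produced seeds to the next
#'     autumn.}
#'   \item{alpha1, beta1}{reproductive intercept and slope: logistic-scale
#'     coefficients of the probability that a germinant reproduces, as a
#'     function of log-precipitation `log(P + 1)`.}
#'   \item{log_alpha2, beta2}{log-yield intercept and slope: coefficients of
#'     the log-linear regression of low-density yield on log-precipitation,
#'     `log(K) = log_alpha2 + beta2 * log(P + 1)`.}
#'   \item{a}{intraspecific competition coefficient (m^2 per seedling);
#'     realized yield is `K / (1 + a * N)` at seedling density `N`.}
#' }
#'
#' @return A tibble with 10 rows and 8 columns.
#' @seealso [read_species_params()] for reading user-supplied tables.
#' @export
#' @examples
#' desert_annuals()
desert_annuals <- function() {
  read_species_params(
    system.file("extdata", "species_params.csv", package = "bethedgr")
  )
}

species_param_cols <- c(
  "species_code", "s_old", "s_new", "alpha1", "beta1",
  "log_alpha2", "beta2", "a"
)

#' Validate a species-parameter table
#'
#' Checks column presence, numeric type, finiteness, and the biological
#' range constraints (survival probabilities in (0,1), competition
#' coefficient positive). Errors name the offending row and column.
#'
#' @param params a data frame with the columns of [desert_annuals()].
#' @return the input, invisibly coerced to a tibble, for piping.
#' @export
validate_species_params <- function(params) {
  if (!is.data.frame(params) || nrow(params) == 0) {
    abort("species parameter table must be a data frame with at least one row")
  }
  missing <- setdiff(species_param_cols, names(params))
  if (length(missing) > 0) {
    abort(paste0("species parameter table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  params <- tibble::as_tibble(params)
  num_cols <- setdiff(species_param_cols, "species_code")
  for (col in num_cols) {
    x <- params[[col]]
    if (!is.numeric(x)) {
      abort(paste0("column '", col, "' must be numeric"))
    }
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      abort(paste0("non-finite value in column '", col, "', row ", bad[1]))
    }
  }
  check_range <- function(col, lo, hi, lo_open = TRUE, hi_open = TRUE) {
    x <- params[[col]]
    bad <- which((if (lo_open) x <= lo else x < lo) |
                   (if (hi_open) x >= hi else x > hi))
    if (length(bad) > 0) {
      abort(paste0("column '", col, "' out of range (", lo, ", ", hi,
                   ") in row ", bad[1],
                   " (species ", params$species_code[bad[1]], ")"))
    }
  }
  check_range("s_old", 0, 1)
  check_range("s_new", 0, 1)
  check_range("a", 0, Inf)
  invisible(params)
}

# Coerce a one-row data frame / named list to a plain named list of
# species parameters; shared by the scalar model functions.
as_species <- function(params) {
  if (is.data.frame(params)) {
    if (nrow(params) != 1) {
      abort("expected a single species (one-row data frame)")
    }
    params <- as.list(params)
  }
  needed <- setdiff(species_param_cols, "species_code")
  missing <- setdiff(needed, names(params))
  if (length(missing) > 0) {
    abort(paste0("species parameters lack field(s): ",
                 paste(missing, collapse = ", ")))
  }
  params
}
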