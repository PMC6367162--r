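#' Invasion growth rate of a rare mutant strategy
#'
#' The stochastic growth rate of a rare mutant with germination fraction
#' `mutant_g` invading a resident population at stationarity with fraction
#' `g`:
#' `r(g, g~) = E[ log( g~ K_t s_new / (1 + a g n_t) + (1 - g~) s_old ) ]`,
#' averaged over a stationary run, pairing each year's yield `K_t` with
#' that year's pre-update resident density `n_t`. Negative values mean the
#' mutant cannot invade.
#'
#' @param stationary a [estimate_stationary()] run for the resident.
#' @param mutant_g mutant germination fraction in `[0, 1]`.
#' @param resident_g optional; if supplied it must equal the `g` the
#'   stationary run was produced with (guards against mismatched runs).
#' @return a list with `r` (the time-average), `se` (naive Monte-Carlo
#'   standard error), `resident_g`, `mutant_g`.
#' @export
invasion_growth_rate <- function(stationary, mutant_g, resident_g = NULL) {
  g <- stationary_g(stationary, resident_g)
  p <- attr(stationary, "params")
  if (mutant_g < 0 || mutant_g > 1) abort("mutant_g must lie in [0, 1]")
  q <- stationary$K * p$s_new / (1 + p$a * g * stationary$n)
  lg <- log(mutant_g * q + (1 - mutant_g) * p$s_old)
  list(r = mean(lg), se = sd(lg) / sqrt(length(lg)),
       resident_g = g, mutant_g = mutant_g)
}

#' Selection gradient on the germination fraction
#'
#' The derivative of the invasion growth rate in the mutant trait,
#' evaluated at the resident (`h(g)`): the time-average of
#' `(Q_t - s_old) / (g Q_t + (1 - g) s_old)` with
#' `Q_t = K_t s_new / (1 + a g n_t)`, obtained by differentiating the
#' invasion growth rate under the expectation. Its interior root is the
#' candidate ESS.
#'
#' @inheritParams invasion_growth_rate
#' @return a list with `h`, `se`, `r_resident` (the realized resident
#'   growth rate over the run, approximately 0 at stationarity) and its
#'   `r_se`.
#' @export
selection_gradient <- function(stationary, resident_g = NULL) {
  g <- stationary_g(stationary, resident_g)
  p <- attr(stationary, "params")
  q <- stationary$K * p$s_new / (1 + p$a * g * stationary$n)
  w <- g * q + (1 - g) * p$s_old
  hterm <- (q - p$s_old) / w
  list(h = mean(hterm), se = sd(hterm) / sqrt(length(hterm)),
       r_resident = mean(log(w)), r_se = sd(log(w)) / sqrt(length(w)))
}

stationary_g <- function(stationary, resident_g) {
  if (!inherits(stationary, "stationary_run")) {
    abort("expected a stationary_run from estimate_stationary()")
  }
  g <- attr(stationary, "g")
  if (!is.null(resident_g) && abs(resident_g - g) > 1e-12) {
    abort("stationary run was generated with a different resident g")
  }
  g
}

# Evaluate h(g) (and diagnostics) on a fixed yield stream: the common-
# random-numbers kernel behind find_ess. Nonpersistent residents (r <= 0)
# are evaluated against n-hat = 0.
ess_eval <- function(g, K, params, burn_in, years, n0) {
  p <- params
  r0 <- growth_rate_from_K(K, g, p)
  post <- (burn_in + 1):(burn_in + years)
  persistent <- r0 > 0
  nq <- if (persistent && g > 0) {
    seedbank_path_cpp(n0, g, K, p$s_new, p$s_old, p$a)[post]
  } else {
    0
  }
  q <- K[post] * p$s_new / (1 + p$a * g * nq)
  w <- g * q + (1 - g) * p$s_old
  hterm <- (q - p$s_old) / w
  list(h = mean(hterm), h_se = sd(hterm) / sqrt(years),
       r_resident = mean(log(w)), r_se = sd(log(w)) / sqrt(years),
       persistent = persistent, r0 = r0)
}

#' Solve for the evolutionarily stable germination fraction
#'
#' Finds the root of the selection gradient `h(g)` on (0, 1) by bisection,
#' using common random numbers: one precipitation/yield stream is drawn
#' from `seed` and reused for every candidate `g`, with the resident
#' re-equilibrated at each candidate. Because the invasion growth rate is
#' strictly concave in the mutant trait, an interior root is unique and is
#' the ESS.
#'
#' Boundary outcomes: if `h(g) > 0` across all of (0, 1] the ESS is full
#' germination (`g_ess = 1`, `boundary_flag = "g_equals_1"`); if no
#' candidate `g` persists (`r <= 0` everywhere) the species cannot maintain
#' a population and `g_ess` is `NA` with `boundary_flag = "nonpersistent"`.
#' For candidate residents that do not persist, the gradient is evaluated
#' against a zero resident density.
#'
#' @inheritParams estimate_stationary
#' @param tol bisection tolerance on `g` (default 1e-3).
#' @param scan_points number of pre-scan points on (0, 1) used to bracket
#'   the root (default 21).
#' @return an object of class `ess_result`: a list with `g_ess`,
#'   `boundary_flag` (`"interior"`, `"g_equals_1"` or `"nonpersistent"`),
#'   `h_at_ess`, `h_se`, `r_resident`, `r_resident_se`, the table of
#'   evaluated gradients (`h_path`), and the run configuration.
#' @seealso [verify_ess()], [find_ess_all()]
#' @export
find_ess <- function(params, precip_model, tol = 1e-3, seed = NULL,
                     burn_in = 1000, years = 50000, n0 = 100,
                     residual_sd = 0, scan_points = 21) {
  if (tol <= 0) abort("tol must be positive")
  p <- as_species_coefs(params,
                        c("alpha1", "beta1", "log_alpha2", "beta2",
                          "s_new", "s_old", "a"))
  total <- burn_in + years
  draw <- function() {
    precip <- draw_precip(precip_model, total)
    sample_low_density_yield(p, precip, residual_sd = residual_sd)
  }
  K <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  evals <- list()
  h_of <- function(g) {
    e <- ess_eval(g, K, p, burn_in, years, n0)
    evals[[length(evals) + 1]] <<- tibble::tibble(
      g = g, h = e$h, h_se = e$h_se, persistent = e$persistent, r0 = e$r0
    )
    e
  }

  g_scan <- c(seq_len(scan_points) / (scan_points + 1), 1)
  scan <- purrr::map(g_scan, h_of)
  h_scan <- vapply(scan, `[[`, numeric(1), "h")
  persistent_scan <- vapply(scan, `[[`, logical(1), "persistent")

  finish <- function(g_ess, flag, eval) {
    structure(
      list(
        g_ess = g_ess, boundary_flag = flag,
        h_at_ess = eval$h, h_se = eval$h_se,
        r_resident = eval$r_resident, r_resident_se = eval$r_se,
        h_path = dplyr::bind_rows(evals),
        tol = tol, seed = seed, burn_in = burn_in, years = years,
        n0 = n0, residual_sd = residual_sd,
        params = p, precip_model = as_precip_model(precip_model)
      ),
      class = "ess_result"
    )
  }

  if (!any(persistent_scan)) {
    return(finish(NA_real_, "nonpersistent", scan[[length(scan)]]))
  }
  if (all(h_scan > 0)) {
    return(finish(1, "g_equals_1", scan[[length(scan)]]))
  }

  # h is decreasing in g under common random numbers: bracket at the first
  # non-positive scan value and bisect
  i <- which(h_scan <= 0)[1]
  lo <- if (i == 1) 1e-6 else g_scan[i - 1]
  hi <- g_scan[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (h_of(mid)$h > 0) lo <- mid else hi <- mid
  }
  g_ess <- (lo + hi) / 2
  finish(g_ess, "interior", h_of(g_ess))
}

#' @export
print.ess_result <- function(x, ...) {
  cat("<ess_result> g_ess = ",
      ifelse(is.na(x$g_ess), "NA", signif(x$g_ess, 4)),
      " (", x$boundary_flag, "), h(g_ess) = ", signif(x$h_at_ess, 3),
      " +/- ", signif(x$h_se, 2), "\n", sep = "")
  cat("  resident realized growth ", signif(x$r_resident, 3),
      " (se ", signif(x$r_resident_se, 2), "); ",
      nrow(x$h_path), " gradient evaluations, tol ", x$tol, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ess_result <- function(x, ...) x$h_path

#' @export
glance.ess_result <- function(x, ...) {
  tibble::tibble(
    g_ess = x$g_ess, boundary_flag = x$boundary_flag,
    h_at_ess = x$h_at_ess, h_se = x$h_se,
    r_resident = x$r_resident, r_resident_se = x$r_resident_se,
    tol = x$tol, burn_in = x$burn_in, years = x$years,
    residual_sd = x$residual_sd, n_evals = nrow(x$h_path)
  )
}

#' Solve the ESS for every species in a parameter table
#'
#' Maps [find_ess()] over the rows of a species-parameter table, deriving
#' one sub-seed per species from `seed`.
#'
#' @param species a species-parameter table ([desert_annuals()] or
#'   compatible).
#' @inheritParams find_ess
#' @return a tibble with one row per species: `species_code`, `g_ess`,
#'   `boundary_flag`, `h_at_ess`, `h_se`, `r_resident`, `r_resident_se`,
#'   and a list-column `result` of the full `ess_result` objects.
#' @export
find_ess_all <- function(species, precip_model, tol = 1e-3, seed = NULL,
                         burn_in = 1000, years = 50000, n0 = 100,
                         residual_sd = 0) {
  species <- validate_species_params(species)
  purrr::map_dfr(seq_len(nrow(species)), function(i) {
    sub_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    res <- find_ess(species[i, ], precip_model, tol = tol, seed = sub_seed,
                    burn_in = burn_in, years = years, n0 = n0,
                    residual_sd = residual_sd)
    dplyr::bind_cols(
      tibble::tibble(species_code = species$species_code[i]),
      dplyr::select(glance(res), "g_ess":"r_resident_se"),
      tibble::tibble(result = list(res))
    )
  })
}

#' Check uninvadability of a solved ESS
#'
#' Re-equilibrates the resident at `g_ess` (same seed and run configuration
#' as the solve) and evaluates the invasion growth rate of mutants on a
#' grid of germination fractions. For a converged ESS every mutant other
#' than the resident itself should have `r < 0` beyond Monte-Carlo noise.
#'
#' @param result an `ess_result` with a defined `g_ess`.
#' @param grid mutant germination fractions to test (default 21 equally
#'   spaced points on `[0, 1]`).
#' @param se_mult how many standard errors above 0 count as a flagged
#'   invasion (default 3).
#' @return a tibble with columns `mutant_g`, `r`, `se`, `invades`, and
#'   attributes `max_r` (over mutants differing from `g_ess`) and
#'   `resident_g`.
#' @export
verify_ess <- function(result, grid = seq(0, 1, length.out = 21),
                       se_mult = 3) {
  stopifnot(inherits(result, "ess_result"))
  if (is.na(result$g_ess)) {
    abort("cannot verify a nonpersistent result: no resident to invade")
  }
  stat <- estimate_stationary(
    result$params, result$g_ess, result$precip_model,
    burn_in = result$burn_in, years = result$years, n0 = result$n0,
    residual_sd = result$residual_sd, seed = result$seed
  )
  out <- purrr::map_dfr(grid, function(gm) {
    inv <- invasion_growth_rate(stat, gm)
    tibble::tibble(mutant_g = gm, r = inv$r, se = inv$se)
  })
  out <- dplyr::mutate(
    out,
    invades = .data$r > se_mult * .data$se &
      abs(.data$mutant_g - result$g_ess) > result$tol
  )
  others <- out$mutant_g[abs(out$mutant_g - result$g_ess) > result$tol]
  attr(out, "max_r") <- max(out$r[out$mutant_g %in% others], -Inf)
  attr(out, "resident_g") <- result$g_ess
  out
}
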