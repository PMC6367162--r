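# simulate a multi-species stage dataset straight from the hurdle structure
sim_stage_data <- function(species, n_per_species, seed,
                           residual_sd = 0.5) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(species)), function(i) {
      sp <- species[i, ]
      x <- log_precip(rlnorm(n_per_species, log(10), 0.5))
      pi_t <- stats::plogis(sp$alpha1 + sp$beta1 * x)
      tibble::tibble(
        species_code = sp$species_code,
        log_precip = x,
        success = runif(n_per_species) < pi_t,
        log_K = sp$log_alpha2 + sp$beta2 * x + rnorm(n_per_species, 0, residual_sd)
      )
    })
  })
}

test_that("balanced symmetric data gives a zero logit line", {
  d <- tibble::tibble(
    species_code = "S",
    log_precip = rep(c(1, 2), each = 10),
    success = rep(c(TRUE, FALSE), 10)
  )
  fit <- fit_binomial_stage(d)
  expect_equal(unname(coef(fit$fit)), c(0, 0), tolerance = 1e-6)
})

test_that("binomial stage recovers generating coefficients with near-nominal coverage", {
  sp <- demo_species(alpha1 = -2, beta1 = 2)
  covered <- matrix(NA, 100, 2)
  for (r in seq_len(100)) {
    d <- sim_stage_data(sp, 500, seed = 1000 + r)
    fit <- fit_binomial_stage(d)$fit
    est <- coef(fit); se <- sqrt(diag(vcov(fit)))
    covered[r, ] <- abs(est - c(-2, 2)) <= 1.96 * se
  }
  expect_gte(mean(covered[, 1]), 0.90)
  expect_gte(mean(covered[, 2]), 0.90)
})

test_that("model forms are nested: full never has lower log-likelihood", {
  species3 <- dplyr::bind_rows(
    demo_species(alpha1 = -3, beta1 = 2.5, log_alpha2 = 0.5, beta2 = 1.2,
                 species_code = "A"),
    demo_species(alpha1 = -2, beta1 = 1.5, log_alpha2 = -0.5, beta2 = 2,
                 species_code = "B"),
    demo_species(alpha1 = -4, beta1 = 3, log_alpha2 = 1, beta2 = 0.9,
                 species_code = "C")
  )
  d <- sim_stage_data(species3, 60, seed = 5)
  for (fitter in list(fit_binomial_stage,
                      function(x, f) fit_yield_stage(dplyr::filter(x, success), f))) {
    fits <- purrr::map(c("full", "common_slope", "common_intercept"),
                       ~ suppressWarnings(fitter(d, .x)))
    ll <- purrr::map_dbl(fits, ~ glance(.x)$loglik)
    expect_gte(ll[1] + 1e-8, ll[2])
    expect_gte(ll[1] + 1e-8, ll[3])
    cmp <- compare_submodels(fits)
    expect_true(all(cmp$lr_stat >= -1e-8))
    # information criteria identities: aic = 2k - 2ll, bic = k log(n) - 2ll
    expect_equal(cmp$aic, 2 * cmp$k - 2 * cmp$loglik)
    expect_equal(cmp$bic, cmp$k * log(cmp$n) - 2 * cmp$loglik)
  }
})

test_that("yield stage reproduces an exact two-point line", {
  d <- tibble::tibble(
    species_code = "S",
    log_precip = c(1, 1, 2, 2),
    log_K = c(1, 1, 3, 3)
  )
  fit <- fit_yield_stage(d)
  expect_equal(unname(coef(fit$fit)), c(-1, 2), tolerance = 1e-10)
  expect_equal(glance(fit)$residual_sd, 0, tolerance = 1e-10)
})

test_that("yield stage equals the normal-equations solution and recovers truth", {
  sp <- demo_species(log_alpha2 = -0.7, beta2 = 2)
  d <- dplyr::filter(sim_stage_data(sp, 200, seed = 9), success)
  fit <- fit_yield_stage(d)
  X <- cbind(1, d$log_precip)
  beta_oracle <- drop(solve(crossprod(X), crossprod(X, d$log_K)))
  expect_equal(unname(coef(fit$fit)), beta_oracle, tolerance = 1e-10)
  td <- tidy(fit)
  expect_true(all(abs(td$estimate - c(-0.7, 2)) <= 3 * td$std.error))
})

test_that("yield stage errors when a line is rank deficient", {
  d <- tibble::tibble(species_code = "S", log_precip = c(1, 1, 1),
                      log_K = c(1, 2, 3))
  expect_error(fit_yield_stage(d), "rank")
})

test_that("binomial stage flags separation and rejects degenerate inputs", {
  d <- tibble::tibble(
    species_code = rep(c("A", "B"), each = 6),
    log_precip = rep(c(1, 2, 3), 4),
    success = c(rep(TRUE, 6), rep(c(TRUE, FALSE), 3))
  )
  expect_warning(fit_binomial_stage(d, "full"), "separation|diverging")
  expect_error(fit_binomial_stage(tibble::tibble()), "non-empty")
  all_success <- tibble::tibble(species_code = "A", log_precip = 1:4,
                                success = TRUE)
  expect_error(fit_binomial_stage(all_success), "at least one")
})

test_that("a genuinely common slope wins AIC in most replicates", {
  species2 <- dplyr::bind_rows(
    demo_species(log_alpha2 = 1, beta2 = 1.5, species_code = "A"),
    demo_species(log_alpha2 = -0.5, beta2 = 1.5, species_code = "B")
  )
  wins <- 0L
  for (r in seq_len(100)) {
    d <- dplyr::filter(sim_stage_data(species2, 25, seed = 2000 + r), success)
    fits <- purrr::map(c("full", "common_slope"), ~ fit_yield_stage(d, .x))
    cmp <- compare_submodels(fits)
    wins <- wins + (cmp$model_form[1] == "common_slope")
  }
  expect_gt(wins, 50)
})

test_that("compare_submodels detects mismatched data and reports ties", {
  sp <- demo_species()
  d1 <- dplyr::filter(sim_stage_data(sp, 50, seed = 1), success)
  d2 <- dplyr::filter(sim_stage_data(sp, 50, seed = 2), success)
  f1 <- fit_yield_stage(d1)
  expect_error(compare_submodels(f1, fit_yield_stage(d2)), "identical data")
  dup <- compare_submodels(f1, fit_yield_stage(d1))
  expect_equal(dup$aic[1], dup$aic[2])
})

test_that("pairwise Wald tests match the covariance formula", {
  species3 <- dplyr::bind_rows(
    demo_species(alpha1 = -1, species_code = "A"),
    demo_species(alpha1 = -2.5, species_code = "B"),
    demo_species(alpha1 = -4, species_code = "C")
  )
  d <- sim_stage_data(species3, 150, seed = 3)
  fit <- fit_binomial_stage(d, "common_slope")
  w <- pairwise_wald(fit, "intercept")
  expect_equal(nrow(w), 3)

  b <- coef(fit$fit); V <- vcov(fit$fit)
  nm <- paste0("species_code", c("A", "B"))
  z_hand <- (b[[nm[1]]] - b[[nm[2]]]) /
    sqrt(V[nm[1], nm[1]] + V[nm[2], nm[2]] - 2 * V[nm[1], nm[2]])
  row_ab <- dplyr::filter(w, species_i == "A", species_j == "B")
  expect_equal(row_ab$z, z_hand)
  expect_equal(row_ab$p_value, 2 * pnorm(-abs(z_hand)))
  expect_true(all(w$p_bonferroni >= w$p_value))

  # two species with identical data: z ~ 0, p ~ 1
  d_eq <- sim_stage_data(demo_species(species_code = "A"), 100, seed = 4)
  d_eq <- dplyr::bind_rows(d_eq, dplyr::mutate(d_eq, species_code = "B"))
  w_eq <- pairwise_wald(fit_binomial_stage(d_eq, "common_slope"), "intercept")
  expect_equal(w_eq$z, 0, tolerance = 1e-6)
  expect_equal(w_eq$p_value, 1, tolerance = 1e-6)

  # shared coefficients cannot be compared
  expect_error(pairwise_wald(fit_binomial_stage(d, "common_slope"), "slope"),
               "no species-specific")
})
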