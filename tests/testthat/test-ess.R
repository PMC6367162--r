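test_that("dormant mutants grow at log(s_old) exactly", {
  sp <- two_point_species(s_old = 0.8)
  stat <- estimate_stationary(sp, 0.6, fixed_precip(), burn_in = 300,
                              years = 5000, seed = 1)
  inv <- invasion_growth_rate(stat, mutant_g = 0)
  expect_equal(inv$r, log(0.8))
  expect_equal(inv$se, 0)
})

test_that("the resident cannot invade itself", {
  sp <- two_point_species()
  stat <- estimate_stationary(sp, 0.6, fixed_precip(), burn_in = 500,
                              years = 20000, seed = 2)
  inv <- invasion_growth_rate(stat, mutant_g = 0.6)
  expect_lt(abs(inv$r), 3 * inv$se)
  expect_error(invasion_growth_rate(stat, 0.5, resident_g = 0.4), "different resident")
})

test_that("constant-environment invasion matches the equilibrium algebra", {
  # at equilibrium g Q + (1 - g) s_old = 1, so Q = (1 - (1-g) s_old) / g = 1.5
  sp <- constant_yield_species(K = 20, s_old = 0.5, s_new = 0.15, a = 0.01)
  stat <- estimate_stationary(sp, 0.5, fixed_precip(), burn_in = 2000,
                              years = 100, seed = 1)
  inv <- invasion_growth_rate(stat, mutant_g = 1)
  expect_equal(inv$r, log(1.5), tolerance = 1e-6)

  grad <- selection_gradient(stat)
  expect_equal(grad$h, (1 - 0.5) / 0.5, tolerance = 1e-6) # (1 - s_old)/g
  expect_lt(abs(grad$r_resident), 1e-6)
})

test_that("the analytic gradient matches a finite difference of invasion fitness", {
  sp <- two_point_species()
  g <- 0.55
  stat <- estimate_stationary(sp, g, fixed_precip(), burn_in = 500,
                              years = 10000, seed = 3)
  grad <- selection_gradient(stat)
  eps <- 1e-5
  fd <- (invasion_growth_rate(stat, g + eps)$r -
           invasion_growth_rate(stat, g - eps)$r) / (2 * eps)
  expect_equal(grad$h, fd, tolerance = 1e-6)
})

test_that("high dormant-seed survival favours dormancy", {
  # with a very safe seed bank the gradient turns negative just above the
  # root, and the ESS drops relative to a riskier bank
  safe <- two_point_species(K_success = 60, s_old = 0.97)
  risky <- two_point_species(K_success = 60, s_old = 0.80)
  res_safe <- find_ess(safe, fixed_precip(), seed = 5, burn_in = 300,
                       years = 10000)
  res_risky <- find_ess(risky, fixed_precip(), seed = 5, burn_in = 300,
                        years = 10000)
  expect_identical(res_safe$boundary_flag, "interior")
  expect_lt(res_safe$g_ess, res_risky$g_ess)
  above <- dplyr::filter(res_safe$h_path, g > res_safe$g_ess + 0.05)
  expect_true(all(above$h < 0))
})

test_that("a constant environment drives the ESS to full germination", {
  sp <- constant_yield_species(K = 10)
  res <- find_ess(sp, fixed_precip(), seed = 1, burn_in = 200, years = 2000)
  expect_identical(res$g_ess, 1)
  expect_identical(res$boundary_flag, "g_equals_1")
  expect_true(all(res$h_path$h > 0))
})

test_that("hopeless species are reported as nonpersistent", {
  sp <- demo_species(log_alpha2 = -4, beta2 = 0.2, s_old = 0.6, s_new = 0.1)
  res <- find_ess(sp, sonoran_precip_model(), seed = 1, burn_in = 100,
                  years = 2000)
  expect_identical(res$boundary_flag, "nonpersistent")
  expect_true(is.na(res$g_ess))
  expect_error(verify_ess(res), "nonpersistent")
})

test_that("the interior ESS zeroes the gradient and resists all mutants", {
  sp <- two_point_species()
  res <- find_ess(sp, fixed_precip(), seed = 4, burn_in = 500, years = 20000)
  expect_identical(res$boundary_flag, "interior")
  expect_true(res$g_ess > 0 && res$g_ess < 1)
  # gradient is (numerically) zero at the root on its own stream
  expect_lt(abs(res$h_at_ess), 3 * res$h_se)
  # the resident realizes zero growth at stationarity
  expect_lt(abs(res$r_resident), 3 * res$r_resident_se)

  prof <- verify_ess(res)
  expect_false(any(prof$invades))
  non_self <- dplyr::filter(prof, abs(mutant_g - res$g_ess) > 0.1)
  expect_true(all(non_self$r < 0))
  # concavity in the mutant trait: second differences non-positive up to noise
  d2 <- diff(prof$r, differences = 2)
  expect_true(all(d2 < 3 * max(prof$se)))
})

test_that("durable seed banks and steep wet-year yields lower the ESS; dry-year success raises it", {
  m <- sonoran_precip_model()
  base <- list(seed = 9, burn_in = 300, years = 8000)
  ess_of <- function(sp) {
    do.call(find_ess, c(list(params = sp, precip_model = m), base))$g_ess
  }
  g_s <- purrr::map_dbl(c(0.3, 0.5, 0.7), ~ ess_of(demo_species(s_old = .x)))
  expect_true(all(diff(g_s) <= 1e-3))
  g_b <- purrr::map_dbl(c(1.3, 1.65, 2.0), ~ ess_of(demo_species(beta2 = .x)))
  expect_true(all(diff(g_b) <= 1e-3))
  g_a <- purrr::map_dbl(c(-4.5, -3.4, -2.3), ~ ess_of(demo_species(alpha1 = .x)))
  expect_true(all(diff(g_a) >= -1e-3))
})
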