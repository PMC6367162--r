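test_that("one seed-bank step matches the recursion algebra", {
  sp <- list(s_new = 0.15, s_old = 0.5, a = 0.01)
  expect_equal(step_seedbank(100, g = 0.5, K = 10, params = sp), 75)
  # dormant-only and full-germination branches
  expect_equal(step_seedbank(80, g = 0, K = 5, params = sp), 0.5 * 80)
  expect_equal(step_seedbank(80, g = 1, K = 5, params = sp),
               5 * 0.15 * 80 / (1 + 0.01 * 80))
  expect_equal(step_seedbank(0, g = 0.5, K = 10, params = sp), 0)
  expect_error(step_seedbank(-1, g = 0.5, K = 10, params = sp))
  expect_error(step_seedbank(10, g = 1.5, K = 10, params = sp))
})

test_that("the step is increasing in K and decreasing in a", {
  base <- list(s_new = 0.15, s_old = 0.5, a = 0.01)
  n <- 120
  k_seq <- purrr::map_dbl(c(2, 5, 10, 30), ~ step_seedbank(n, 0.4, .x, base))
  expect_true(all(diff(k_seq) > 0))
  a_seq <- purrr::map_dbl(c(0.001, 0.01, 0.05), function(a) {
    step_seedbank(n, 0.4, 10, modifyList(base, list(a = a)))
  })
  expect_true(all(diff(a_seq) < 0))
})

test_that("the compiled path equals iterating the R step", {
  sp <- demo_species()
  run <- simulate_seedbank(sp, g = 0.6, fixed_precip(c(4, 9, 14, 6)),
                           years = 40, n0 = 50, seed = 3)
  n_r <- numeric(40)
  n_cur <- 50
  for (t in 1:40) {
    n_r[t] <- n_cur
    n_cur <- step_seedbank(n_cur, 0.6, run$K[t], sp)
  }
  expect_equal(run$n, n_r)
  expect_equal(run$n_next[40], n_cur)
})

test_that("trajectories are positive, reproducible, and decay when r < 0", {
  sp <- demo_species()
  m <- sonoran_precip_model()
  r1 <- simulate_seedbank(sp, 0.5, m, years = 300, seed = 11)
  r2 <- simulate_seedbank(sp, 0.5, m, years = 300, seed = 11)
  expect_identical(r1$n, r2$n)
  expect_true(all(r1$n > 0))

  # g = 0: pure geometric decay at rate log(s_old)
  r0 <- simulate_seedbank(sp, 0, m, years = 100, n0 = 100, seed = 1)
  expect_equal(r0$n_next[100], 100 * 0.5^100)
  expect_lt(r0$n_next[100], 1e-6 * 100)
})

test_that("constant environments converge to the positive fixed point", {
  # g K s_new + (1-g) s_old = 1.75 > 1: persistent, fixed point n* = 200
  sp <- constant_yield_species(K = 20, s_old = 0.5, s_new = 0.15, a = 0.01)
  g <- 0.5
  n_star <- constant_env_fixed_point(g, 20, 0.15, 0.5, 0.01)
  expect_equal(n_star, 200)
  run <- simulate_seedbank(sp, g, fixed_precip(10), years = 400, n0 = 5,
                           seed = 1)
  expect_equal(run$n_next[400], n_star, tolerance = 1e-8)
})

test_that("low-density growth rate has the stated closed forms", {
  sp <- demo_species(s_old = 0.5)
  expect_equal(low_density_growth_rate(sp, 0, fixed_precip())$r, log(0.5))

  const <- constant_yield_species(K = 10, s_old = 0.5, s_new = 0.15)
  expect_equal(low_density_growth_rate(const, 0.5, fixed_precip(), years = 50)$r,
               0, tolerance = 1e-12) # 0.5*10*0.15 + 0.5*0.5 = 1 exactly

  # two-point environment: r = 0.5 log(0.5 s_new) + 0.5 log(20 s_new) at g = 1
  tp <- two_point_species(K_success = 20, s_new = 0.15)
  ldg <- low_density_growth_rate(tp, 1, fixed_precip(), years = 40000, seed = 2)
  r_exact <- 0.5 * log(0.5 * 0.15) + 0.5 * log(20 * 0.15)
  expect_equal(r_exact, -0.7459, tolerance = 1e-4)
  expect_lt(abs(ldg$r - r_exact), 3 * ldg$se)
})

test_that("stationary runs are stationary", {
  sp <- two_point_species()
  m <- fixed_precip()
  stat <- estimate_stationary(sp, 0.6, m, burn_in = 500, years = 8000, seed = 5)
  expect_true(all(stat$n > 0))
  # realized growth over the run is zero within Monte-Carlo error
  lr <- log(stat$n_next / stat$n)
  expect_lt(abs(mean(lr)), 3 * sd(lr) / sqrt(length(lr)))
  # doubling the run leaves the mean density unchanged within error
  stat2 <- estimate_stationary(sp, 0.6, m, burn_in = 500, years = 16000, seed = 6)
  se_pool <- sd(stat$n) / sqrt(200) # generous: heavy autocorrelation
  expect_lt(abs(mean(stat$n) - mean(stat2$n)), 3 * se_pool)
  # insensitive to the starting density
  stat3 <- estimate_stationary(sp, 0.6, m, burn_in = 500, years = 8000,
                               n0 = 5000, seed = 5)
  expect_equal(mean(stat$n), mean(stat3$n), tolerance = 0.02)
})

test_that("two independent stationary runs agree in distribution", {
  sp <- two_point_species()
  m <- fixed_precip()
  s1 <- estimate_stationary(sp, 0.6, m, burn_in = 500, years = 20000, seed = 21)
  s2 <- estimate_stationary(sp, 0.6, m, burn_in = 500, years = 20000, seed = 22)
  thin <- seq(1, 20000, by = 50) # break autocorrelation before the KS test
  ks <- suppressWarnings(stats::ks.test(s1$n[thin], s2$n[thin]))
  expect_gt(ks$p.value, 1e-3)
})

test_that("nonpersistent residents are refused with a clear error", {
  sp <- demo_species(log_alpha2 = -4, beta2 = 0.2, s_old = 0.6)
  expect_error(
    estimate_stationary(sp, 0.8, sonoran_precip_model(), burn_in = 100,
                        years = 500, seed = 1),
    "not persistent|extinct"
  )
})

test_that("constant-environment stationary run sits on the fixed point", {
  sp <- constant_yield_species(K = 20)
  stat <- estimate_stationary(sp, 0.5, fixed_precip(), burn_in = 1000,
                              years = 200, seed = 1)
  n_star <- constant_env_fixed_point(0.5, 20, 0.15, 0.5, 0.01)
  expect_true(all(abs(stat$n - n_star) < 1e-6))
})
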