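# Synthetic species used across the test files. All fixtures are built in
# code; none are read from disk.

demo_species <- function(s_old = 0.5, s_new = 0.15, alpha1 = -3.4, beta1 = 2,
                         log_alpha2 = 0, beta2 = 1.5, a = 0.01,
                         species_code = "DEMO") {
  tibble::tibble(species_code = species_code, s_old = s_old, s_new = s_new,
                 alpha1 = alpha1, beta1 = beta1, log_alpha2 = log_alpha2,
                 beta2 = beta2, a = a)
}

# two-point yield environment: K = K_success or 0.5, each with probability 1/2,
# independent of precipitation
two_point_species <- function(K_success = 60, s_old = 0.8, s_new = 0.15,
                              a = 0.01) {
  demo_species(s_old = s_old, s_new = s_new, alpha1 = 0, beta1 = 0,
               log_alpha2 = log(K_success), beta2 = 0, a = a,
               species_code = "TWOPT")
}

# deterministic yield K every year (the reproductive hurdle never fails)
constant_yield_species <- function(K = 10, s_old = 0.5, s_new = 0.15,
                                   a = 0.01) {
  demo_species(s_old = s_old, s_new = s_new, alpha1 = 40, beta1 = 0,
               log_alpha2 = log(K), beta2 = 0, a = a,
               species_code = "CONST")
}

fixed_precip <- function(p = 10) precip_model("fixed", series = p)

# equilibrium density of the constant-environment seed bank:
# g K s_new / (1 + a g n*) + (1 - g) s_old = 1
constant_env_fixed_point <- function(g, K, s_new, s_old, a) {
  (g * K * s_new / (1 - (1 - g) * s_old) - 1) / (a * g)
}
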