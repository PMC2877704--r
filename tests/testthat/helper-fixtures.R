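# shared fixtures: everything is generated in code, nothing read from disk

truth_vector <- function(truth = default_truth()) {
  p <- truth$params
  c(stats::setNames(p$a, paste0("a_", p$prey)),
    stats::setNames(p$t, paste0("t_", p$prey)),
    stats::setNames(p$m, paste0("m_", p$prey)),
    stats::setNames(truth$k, paste0("k_", p$prey)))
}

# wrap a fixed draw matrix as a chains object (for constructed-posterior tests)
chains_from_matrix <- function(draws, prey = NULL, shared_k = FALSE) {
  structure(list(draws = draws, param_names = colnames(draws),
                 acceptance_rates = rep(NA_real_, ncol(draws)),
                 step_sizes_final = rep(NA_real_, ncol(draws)),
                 transforms = NULL, seed = NA_integer_, config = NULL,
                 prey = prey, shared_k = shared_k),
            class = "msfr_chains")
}

# single-prey parameter draws whose mortality curves are known to produce
# three equilibria (predator pit) / one equilibrium under r = 1, K = 208,
# harrier density 0.16, effort scale 336
pit_theta <- c(a_grouse = 0.001, t_grouse = 2, m_grouse = 3, k_grouse = 5)
nopit_theta <- c(a_grouse = 0.0001, t_grouse = 2, m_grouse = 3, k_grouse = 5)

grouse_only_scenario <- function(...) {
  scenario(stats::setNames(numeric(0), character(0)), focal = "grouse", ...)
}

quick_config <- function(n_iterations = 500L, burn_in = 300L, seed = 42L,
                         ...) {
  sampler_config(n_iterations = n_iterations, burn_in = burn_in,
                 seed = seed, ...)
}
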