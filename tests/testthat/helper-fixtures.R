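# Shared fixtures: everything is generated in code at test time.

# A small but complete synthetic study: 2 enzymes x 1 pH each x 2 T x 7 S
small_grid <- function() {
  g <- default_condition_grid(temperatures_C = c(18, 25))
  dplyr::filter(g, replicate == 1L,
                (enzyme == "HRP" & pH == 7) | (enzyme == "heme" & pH == 4))
}

small_expset <- function(master_seed = 11, noise_sd = 0.1) {
  generate_experiment_set(ground_truth_law(), small_grid(),
                          noise_sd = noise_sd, master_seed = master_seed)
}

# Exactly linear calibration points
exact_cal_tbl <- function(slope = 2, concs = seq(10, 70, by = 10)) {
  tibble::tibble(conc_uM = concs, delta_I_uA = slope * concs)
}

# Independent R-squared formula used as an oracle
r2_oracle <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

# Degenerate posterior concentrated at (K_M, k_cat): cheap inversion stand-in
fake_posterior <- function(K_M, k_cat, noise_sd = 0.01, n = 50) {
  structure(list(
    samples = tibble::tibble(chain = 1L, draw = seq_len(n),
                             K_M = K_M, k_cat = k_cat, noise_sd = noise_sd),
    acceptance_rate = 1, n_chains = 1L, n_steps = n, burn_in = 0L,
    rhat = c(K_M = 1, k_cat = 1, noise_sd = 1),
    converged = TRUE, warnings = character(), prior = prior_spec(), seed = 0L),
    class = "mm_posterior")
}

# Synthetic training table with labels from a smooth log-linear law
linear_law_table <- function(n = 200, seed = 17, noise = 0) {
  set.seed(seed)
  tb <- tibble::tibble(
    condition_id = sprintf("c%03d", seq_len(n)),
    enzyme_HRP = rep(c(1, 0), length.out = n),
    enzyme_heme = 1 - rep(c(1, 0), length.out = n),
    substrate_ABTS = 1, substrate_H2O2 = 0,
    pH = runif(n, 4, 7),
    temperature_C = runif(n, 18, 25),
    substrate_conc_uM = runif(n, 25, 1000))
  tb$log_K_M <- 4 + 0.2 * (tb$pH - 5.5) + 0.05 * (tb$temperature_C - 22) +
    0.3 * tb$enzyme_HRP + rnorm(n, 0, noise)
  tb$log_k_cat <- 2 + 0.15 * (tb$temperature_C - 22) - 0.25 * (tb$pH - 5.5) +
    0.5 * tb$enzyme_heme + rnorm(n, 0, noise)
  tb
}
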