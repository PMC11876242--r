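make_data <- function(K_M = 100, k_cat = 10, E_total = 0.01,
                      S = c(25, 50, 100, 250, 500, 750, 1000),
                      rel_noise = 0.01, seed = 1) {
  v <- k_cat * E_total * S / (K_M + S)
  set.seed(seed)
  v_obs <- pmax(v + rnorm(length(S), 0, rel_noise * max(v)), 0)
  rate_dataset(S, v_obs, E_total = E_total)
}

test_that("log_posterior matches hand-computed Gaussian term sums", {
  prior <- prior_spec()
  d <- rate_dataset(c(10, 50, 200, 800), c(0.1, 0.3, 0.5, 0.6), E_total = 0.01)

  # support violations encode as -Inf, never as errors
  expect_identical(log_posterior(c(0.5, 10, 0.1), d, prior), -Inf)   # K_M below bound
  expect_identical(log_posterior(c(100, 1e5, 0.1), d, prior), -Inf)  # k_cat above bound
  expect_identical(log_posterior(c(100, 10, -1), d, prior), -Inf)
  expect_error(log_posterior(c(NA, 1, 1), d, prior), class = "gfetkin_domain_error")

  # zero-residual data: likelihood collapses to -n log(sigma sqrt(2 pi))
  K_M <- 150; k_cat <- 80; sigma <- 0.05
  S <- c(25, 100, 400, 900)
  v <- k_cat * 0.01 * S / (K_M + S)
  d0 <- rate_dataset(S, v, E_total = 0.01)
  lp <- log_posterior(c(K_M, k_cat, sigma), d0, prior)
  lprior <- -log(K_M) - log(log(1e4 / 1)) - log(k_cat) - log(log(1e3 / 1e-2)) +
    0.5 * log(2) - log(1) - 0.5 * log(pi) - sigma^2 / 2
  expect_equal(lp - lprior, -length(S) * log(sigma * sqrt(2 * pi)),
               tolerance = 1e-10)

  # term-by-term oracle on a small dataset with residuals
  d3 <- rate_dataset(c(30, 60, 120, 240), c(0.02, 0.05, 0.07, 0.09),
                     E_total = 0.01)
  theta <- c(120, 15, 0.01)
  mu <- theta[2] * 0.01 * d3$S_uM / (theta[1] + d3$S_uM)
  expect_equal(log_posterior(theta, d3, prior),
               lprior_of <- {
                 -log(theta[1]) - log(log(1e4)) - log(theta[2]) -
                   log(log(1e3 / 1e-2)) + 0.5 * log(2) - 0.5 * log(pi) -
                   theta[3]^2 / 2
               } + sum(dnorm(d3$v0_uM_per_s, mu, theta[3], log = TRUE)),
               tolerance = 1e-10)
})

test_that("rate datasets enforce their invariants", {
  expect_error(rate_dataset(c(1, 1, 2, 3), c(1, 1, 1, 1), 0.1),
               class = "gfetkin_domain_error")
  expect_error(rate_dataset(c(1, 2, 3, 4), c(1, -1, 1, 1), 0.1),
               class = "gfetkin_domain_error")
  expect_error(rate_dataset(c(1, 2, 3, 4), c(1, 1, 1, 1), 0),
               class = "gfetkin_domain_error")
})

test_that("MCMC is deterministic under seed and recovers known parameters", {
  d <- make_data(K_M = 100, k_cat = 10, rel_noise = 0.01, seed = 4)
  a <- run_mcmc(d, n_chains = 2, n_steps = 4000, seed = 99)
  b <- run_mcmc(d, n_chains = 2, n_steps = 4000, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(a$acceptance_rate, b$acceptance_rate)

  s <- summarize_posterior(a)
  expect_lt(abs(s$median[s$parameter == "K_M"] / 100 - 1), 0.1)
  expect_lt(abs(s$median[s$parameter == "k_cat"] / 10 - 1), 0.1)
  # adaptation lands in the targeted acceptance band
  expect_true(all(a$acceptance_rate > 0.1 & a$acceptance_rate < 0.6))
})

test_that("with the likelihood disabled the sampler reproduces the prior", {
  prior <- prior_spec()
  post <- run_mcmc(NULL, prior = prior, n_chains = 4, n_steps = 6000,
                   burn_in = 1000, seed = 7, use_likelihood = FALSE)
  expect_gte(nrow(post$samples), 10000)
  # log-uniform prior quantiles are linear in log space
  for (q in c(0.25, 0.5, 0.75)) {
    expect_equal(unname(quantile(log(post$samples$K_M), q)),
                 log(1) + q * (log(1e4) - log(1)),
                 tolerance = 0.35) # MC error on a 9.2-nat-wide support
    expect_equal(unname(quantile(log(post$samples$k_cat), q)),
                 log(1e-2) + q * (log(1e3) - log(1e-2)),
                 tolerance = 0.45)
  }
})

test_that("posterior summaries are recomputable and match a sort-based oracle", {
  d <- make_data(seed = 8)
  post <- run_mcmc(d, n_chains = 2, n_steps = 2000, seed = 12)
  s <- summarize_posterior(post)
  x <- post$samples$K_M
  sorted <- sort(x)
  expect_equal(s$median[s$parameter == "K_M"],
               median(sorted))
  expect_equal(s$q5[s$parameter == "K_M"],
               unname(quantile(sorted, 0.05)))
  expect_equal(s$mean[s$parameter == "K_M"], sum(x) / length(x))

  # degenerate all-equal samples
  fake <- post
  fake$samples$K_M <- 42
  fs <- summarize_posterior(fake)
  expect_equal(fs$median[fs$parameter == "K_M"], 42)
  expect_equal(fs$mean[fs$parameter == "K_M"], 42)
  expect_equal(fs$sd[fs$parameter == "K_M"], 0)
})

test_that("split-rhat is 1 for identical chains and flags divergent ones", {
  x <- rep(c(1, 3, 2, 5, 4), 100) # stationary: split halves share moments
  expect_equal(gfetkin:::split_rhat(cbind(x, x)), 1)
  divergent <- cbind(rep(0, 500) + rnorm(500, sd = 0.01),
                     rep(10, 500) + rnorm(500, sd = 0.01))
  expect_gt(gfetkin:::split_rhat(divergent), 1.2)
})

test_that("posterior of the turnover number is invariant to concentration rescaling", {
  # same data expressed in uM and in nM, with consistently scaled priors
  K_M <- 120; k_cat <- 20; E <- 0.01
  S_uM <- c(25, 50, 100, 250, 500, 750, 1000)
  v_uM <- k_cat * E * S_uM / (K_M + S_uM)
  set.seed(5)
  noise <- rnorm(7, 0, 0.02 * max(v_uM))
  d_uM <- rate_dataset(S_uM, pmax(v_uM + noise, 0), E_total = E)
  d_nM <- rate_dataset(S_uM * 1e3, pmax((v_uM + noise) * 1e3, 0),
                       E_total = E * 1e3)
  p_uM <- prior_spec()
  p_nM <- prior_spec(K_M = list(dist = "log-uniform", bounds = c(1e3, 1e7)),
                     noise_scale = 1e3)
  a <- run_mcmc(d_uM, p_uM, n_chains = 2, n_steps = 6000, seed = 33)
  b <- run_mcmc(d_nM, p_nM, n_chains = 2, n_steps = 6000, seed = 34)
  ma <- median(a$samples$k_cat)
  mb <- median(b$samples$k_cat)
  expect_equal(mb / ma, 1, tolerance = 0.05)
  # and K_M transforms by exactly the unit factor
  expect_equal(median(b$samples$K_M) / median(a$samples$K_M) / 1e3, 1,
               tolerance = 0.1)
})

test_that("posterior sd of log K_M contracts with more substrate points", {
  K_M <- 100; k_cat <- 10; E <- 0.01
  gen <- function(S, seed) {
    v <- k_cat * E * S / (K_M + S)
    set.seed(seed)
    rate_dataset(S, pmax(v + rnorm(length(S), 0, 0.05 * max(v)), 0), E_total = E)
  }
  S7 <- c(25, 50, 100, 250, 500, 750, 1000)
  S14 <- sort(c(S7, S7 * 1.4))
  sd7 <- vapply(1:5, function(i) {
    sd(log(run_mcmc(gen(S7, 100 + i), n_chains = 2, n_steps = 3000,
                    seed = 200 + i)$samples$K_M))
  }, 0)
  sd14 <- vapply(1:5, function(i) {
    sd(log(run_mcmc(gen(S14, 100 + i), n_chains = 2, n_steps = 3000,
                    seed = 300 + i)$samples$K_M))
  }, 0)
  expect_lt(median(sd14), median(sd7))
})

test_that("tidy and glance expose the standard summaries", {
  d <- make_data(seed = 2)
  post <- run_mcmc(d, n_chains = 2, n_steps = 2000, seed = 3)
  td <- generics::tidy(post)
  expect_setequal(td$parameter, c("K_M", "k_cat", "noise_sd"))
  gl <- generics::glance(post)
  expect_equal(gl$n_chains, 2)
  expect_equal(gl$n_draws, nrow(post$samples))
  expect_true(is.logical(gl$converged))
  ci <- credible_interval(post)
  expect_true(all(ci$lower < ci$upper))
})
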