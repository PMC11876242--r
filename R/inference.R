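#' Prior specification for Michaelis-Menten inversion
#'
#' Priors over the kinetic parameters and the observation noise used by
#' [run_mcmc()]. Each kinetic parameter takes either a log-uniform prior
#' (`bounds = c(lower, upper)` in natural units) or a log-normal prior
#' (`meanlog`, `sdlog` in log space); the rate-noise standard deviation
#' takes a half-normal prior with scale `noise_scale`. All priors put mass
#' on strictly positive values only. Defaults span the peroxidase
#' literature ranges without being informative.
#'
#' @param K_M Prior for the Michaelis constant (uM): a list with `dist`
#'   (`"log-uniform"` or `"log-normal"`) and `bounds` or `meanlog`/`sdlog`.
#' @param k_cat Prior for the turnover number (1/s), same structure.
#' @param noise_scale Half-normal scale for the rate noise sd (uM/s).
#' @return An object of class `prior_spec`.
#' @export
#' @examples
#' prior_spec()  # log-uniform K_M in [1, 1e4] uM, k_cat in [1e-2, 1e3] 1/s
prior_spec <- function(K_M = list(dist = "log-uniform", bounds = c(1, 1e4)),
                       k_cat = list(dist = "log-uniform", bounds = c(1e-2, 1e3)),
                       noise_scale = 1) {
  validate_marginal <- function(m, name) {
    if (!is.list(m) || is.null(m$dist) ||
        !m$dist %in% c("log-uniform", "log-normal")) {
      abort(sprintf("`%s` must specify dist 'log-uniform' or 'log-normal'.", name),
            class = "gfetkin_domain_error")
    }
    if (m$dist == "log-uniform") {
      stopifnot(is.numeric(m$bounds), length(m$bounds) == 2L,
                all(m$bounds > 0), m$bounds[1] < m$bounds[2])
    } else {
      check_scalar(m$meanlog, paste0(name, "$meanlog"))
      check_scalar(m$sdlog, paste0(name, "$sdlog"), positive = TRUE)
    }
    m
  }
  check_scalar(noise_scale, "noise_scale", positive = TRUE)
  structure(list(K_M = validate_marginal(K_M, "K_M"),
                 k_cat = validate_marginal(k_cat, "k_cat"),
                 noise_scale = noise_scale),
            class = "prior_spec")
}

# log prior density of one kinetic-parameter marginal at value x (> 0)
log_prior_marginal <- function(m, x) {
  if (m$dist == "log-uniform") {
    if (x < m$bounds[1] || x > m$bounds[2]) return(-Inf)
    -log(x) - log(log(m$bounds[2] / m$bounds[1]))
  } else {
    stats::dlnorm(x, m$meanlog, m$sdlog, log = TRUE)
  }
}

#' Rate-versus-substrate dataset
#'
#' The observation unit of the inversion: initial rates measured at a
#' series of substrate concentrations under fixed gate and drain voltage,
#' plus the total enzyme concentration that converts the turnover number to
#' a limiting rate.
#'
#' @param S_uM Substrate concentrations, uM (>= 4 distinct values).
#' @param v0_uM_per_s Observed initial rates, uM/s (non-negative).
#' @param E_total Total enzyme concentration, uM.
#' @param condition Optional metadata (list or tibble row) carried along.
#' @return A tibble of class `rate_dataset` with attributes `E_total` and
#'   `condition`.
#' @export
rate_dataset <- function(S_uM, v0_uM_per_s, E_total, condition = NULL) {
  if (length(unique(S_uM)) < 4L) {
    abort("Need at least 4 distinct substrate concentrations.",
          class = "gfetkin_domain_error")
  }
  if (length(S_uM) != length(v0_uM_per_s) || any(v0_uM_per_s < 0) ||
      any(S_uM <= 0)) {
    abort("Rates must be non-negative and aligned with positive S values.",
          class = "gfetkin_domain_error")
  }
  check_scalar(E_total, "E_total", positive = TRUE)
  out <- tibble(S_uM = S_uM, v0_uM_per_s = v0_uM_per_s)
  attr(out, "E_total") <- E_total
  attr(out, "condition") <- condition
  class(out) <- c("rate_dataset", class(out))
  out
}

#' Log posterior density of (K_M, k_cat, noise_sd)
#'
#' Gaussian likelihood of observed initial rates around the closed-form
#' Michaelis-Menten prediction, plus the prior:
#' `log p = log prior(theta) + sum log N(v_obs | V_max S/(K_M + S), noise_sd)`
#' with `V_max = k_cat * E_total`. Support violations return `-Inf` rather
#' than erroring, so samplers can probe freely.
#'
#' @param theta Numeric vector `c(K_M, k_cat, noise_sd)` in natural units.
#' @param data A [rate_dataset()].
#' @param prior A [prior_spec()].
#' @return Single log-density value (possibly `-Inf`).
#' @export
log_posterior <- function(theta, data, prior = prior_spec()) {
  stopifnot(is.numeric(theta), length(theta) == 3L)
  if (anyNA(theta) || any(!is.finite(theta))) {
    abort("`theta` must be finite.", class = "gfetkin_domain_error")
  }
  stopifnot(inherits(data, "rate_dataset"), inherits(prior, "prior_spec"))
  K_M <- theta[1]; k_cat <- theta[2]; noise_sd <- theta[3]
  if (K_M <= 0 || k_cat <= 0 || noise_sd <= 0) return(-Inf)
  lp <- log_prior_marginal(prior$K_M, K_M) +
    log_prior_marginal(prior$k_cat, k_cat) +
    # half-normal on noise_sd
    (0.5 * log(2) - log(prior$noise_scale) - 0.5 * log(pi) -
       noise_sd^2 / (2 * prior$noise_scale^2))
  if (!is.finite(lp)) return(-Inf)
  E_total <- attr(data, "E_total")
  mu <- k_cat * E_total * data$S_uM / (K_M + data$S_uM)
  lp + sum(stats::dnorm(data$v0_uM_per_s, mu, noise_sd, log = TRUE))
}

#' Sample the Michaelis-Menten posterior by adaptive random-walk Metropolis
#'
#' Random-walk Metropolis in log-parameter space
#' `(log K_M, log k_cat, log noise_sd)` with a diagonal Gaussian proposal
#' whose per-coordinate scales are adapted during burn-in only (targeting
#' an acceptance rate of roughly 0.2-0.5); after burn-in the proposal is
#' frozen, so the post-burn-in chain is a valid Metropolis sampler. Chains
#' start from independent prior draws. Fully deterministic under `seed`.
#'
#' @param data A [rate_dataset()], or `NULL` to sample the prior.
#' @param prior A [prior_spec()].
#' @param n_chains Number of chains (>= 2 recommended).
#' @param n_steps Steps per chain (including burn-in).
#' @param burn_in Steps discarded per chain (default half of `n_steps`).
#' @param seed Mandatory integer seed.
#' @param use_likelihood Set `FALSE` to switch the likelihood off (flat),
#'   e.g. for prior-recovery checks.
#' @param rhat_threshold Threshold for the `converged` flag (default 1.1).
#' @return An object of class `mm_posterior`: list with `samples` (tibble
#'   `chain, draw, K_M, k_cat, noise_sd`, post-burn-in), `acceptance_rate`
#'   (per chain, post-burn-in), `n_chains`, `n_steps`, `burn_in`, `rhat`
#'   (per parameter), `converged`, `warnings`, and the `prior`.
#' @export
run_mcmc <- function(data, prior = prior_spec(), n_chains = 4,
                     n_steps = 20000, burn_in = floor(n_steps / 2), seed,
                     use_likelihood = !is.null(data), rhat_threshold = 1.1) {
  stopifnot(inherits(prior, "prior_spec"))
  if (missing(seed)) abort("`seed` is mandatory.", class = "gfetkin_domain_error")
  check_scalar(n_chains, "n_chains", positive = TRUE)
  check_scalar(n_steps, "n_steps", positive = TRUE)
  check_scalar(burn_in, "burn_in", non_negative = TRUE)
  if (burn_in >= n_steps) {
    abort("`burn_in` must be smaller than `n_steps`.",
          class = "gfetkin_domain_error")
  }
  if (use_likelihood) stopifnot(inherits(data, "rate_dataset"))

  # flatten data for the hot loop
  if (use_likelihood) {
    S <- data$S_uM; v <- data$v0_uM_per_s; E_total <- attr(data, "E_total")
  }
  lp_fun <- function(eta) {
    # eta = log theta; include the Jacobian so the chain targets theta-space
    th <- exp(eta)
    K_M <- th[1]; k_cat <- th[2]; noise_sd <- th[3]
    lp <- log_prior_marginal(prior$K_M, K_M) +
      log_prior_marginal(prior$k_cat, k_cat) -
      noise_sd^2 / (2 * prior$noise_scale^2)
    if (!is.finite(lp)) return(-Inf)
    if (use_likelihood) {
      mu <- k_cat * E_total * S / (K_M + S)
      lp <- lp - length(S) * log(noise_sd) -
        sum((v - mu)^2) / (2 * noise_sd^2)
    }
    lp + sum(eta) # Jacobian of the log transform
  }

  draw_prior <- function(m) {
    if (m$dist == "log-uniform") {
      exp(runif(1, log(m$bounds[1]), log(m$bounds[2])))
    } else {
      stats::rlnorm(1, m$meanlog, m$sdlog)
    }
  }

  keep <- n_steps - burn_in
  all_samples <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  warnings_out <- character()

  for (ch in seq_len(n_chains)) {
    with_seed(derive_seed(seed, paste0("chain_", ch)), {
      eta <- log(c(draw_prior(prior$K_M), draw_prior(prior$k_cat),
                   abs(rnorm(1, 0, prior$noise_scale)) + 1e-12))
      lp <- lp_fun(eta)
      step_sd <- rep(0.5, 3)
      acc_window <- 0L
      acc_post <- 0L
      out <- matrix(NA_real_, nrow = keep, ncol = 3)
      for (i in seq_len(n_steps)) {
        prop <- eta + rnorm(3, 0, step_sd)
        lp_prop <- lp_fun(prop)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          eta <- prop; lp <- lp_prop
          acc_window <- acc_window + 1L
          if (i > burn_in) acc_post <- acc_post + 1L
        }
        # adapt during burn-in only, in blocks of 100 steps
        if (i <= burn_in && i %% 100 == 0) {
          rate <- acc_window / 100
          step_sd <- pmin(pmax(step_sd * exp(rate - 0.3), 1e-4), 20)
          acc_window <- 0L
        }
        if (i > burn_in) out[i - burn_in, ] <- eta
      }
      all_samples[[ch]] <- exp(out)
      acc_rates[ch] <- acc_post / keep
      if (acc_post == 0L) {
        warnings_out <- c(warnings_out,
                          sprintf("chain %d accepted no post-burn-in proposals", ch))
      }
    })
  }

  samples <- bind_rows(lapply(seq_len(n_chains), function(ch) {
    tibble(chain = ch, draw = seq_len(keep),
           K_M = all_samples[[ch]][, 1],
           k_cat = all_samples[[ch]][, 2],
           noise_sd = all_samples[[ch]][, 3])
  }))
  rhat <- vapply(c("K_M", "k_cat", "noise_sd"), function(p) {
    split_rhat(matrix(samples[[p]], nrow = keep, ncol = n_chains))
  }, numeric(1))
  if (any(rhat > 1.2)) {
    warnings_out <- c(warnings_out,
                      sprintf("rhat above 1.2 for: %s",
                              paste(names(rhat)[rhat > 1.2], collapse = ", ")))
  }
  structure(list(samples = samples, acceptance_rate = acc_rates,
                 n_chains = n_chains, n_steps = n_steps, burn_in = burn_in,
                 rhat = rhat, converged = all(rhat <= rhat_threshold),
                 warnings = warnings_out, prior = prior, seed = seed),
            class = "mm_posterior")
}

# Split-Rhat (Gelman-Rubin with split chains); clamped at 1 so the
# identical-chain limit reports exactly 1.
split_rhat <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  splits <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  max(1, sqrt(((half - 1) / half * W + B / half) / W))
}

#' @export
print.mm_posterior <- function(x, ...) {
  cat(sprintf("MM posterior: %d chains x %d kept draws (burn-in %d)\n",
              x$n_chains, x$n_steps - x$burn_in, x$burn_in))
  cat(sprintf("  acceptance: %s | converged: %s\n",
              paste(sprintf("%.2f", x$acceptance_rate), collapse = " "),
              x$converged))
  print(summarize_posterior(x))
  invisible(x)
}

#' Posterior summary table
#'
#' @param post An `mm_posterior`.
#' @return Tibble with one row per parameter: `parameter`, `mean`,
#'   `median`, `sd`, `q5`, `q95`, `rhat`. All entries are recomputable
#'   from `post$samples`.
#' @export
summarize_posterior <- function(post) {
  stopifnot(inherits(post, "mm_posterior"))
  if (nrow(post$samples) == 0) {
    abort("Posterior has no retained draws.", class = "gfetkin_domain_error")
  }
  params <- c("K_M", "k_cat", "noise_sd")
  bind_rows(lapply(params, function(p) {
    x <- post$samples[[p]]
    tibble(parameter = p, mean = mean(x), median = median(x), sd = sd(x),
           q5 = unname(quantile(x, 0.05)), q95 = unname(quantile(x, 0.95)),
           rhat = unname(post$rhat[p]))
  }))
}

#' @rdname summarize_posterior
#' @param x An `mm_posterior`.
#' @param ... Unused.
#' @method tidy mm_posterior
#' @export
tidy.mm_posterior <- function(x, ...) summarize_posterior(x)

#' @rdname summarize_posterior
#' @method glance mm_posterior
#' @export
glance.mm_posterior <- function(x, ...) {
  tibble(n_chains = x$n_chains, n_draws = nrow(x$samples),
         burn_in = x$burn_in,
         mean_acceptance = mean(x$acceptance_rate),
         max_rhat = max(x$rhat), converged = x$converged,
         n_warnings = length(x$warnings))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' 90% equal-tailed credible interval per kinetic parameter
#' @param post An `mm_posterior`.
#' @return Tibble `parameter`, `lower`, `upper` (5% and 95% quantiles).
#' @export
credible_interval <- function(post) {
  s <- summarize_posterior(post)
  tibble(parameter = s$parameter, lower = s$q5, upper = s$q95)
}
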