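test_that("mm_rate satisfies its algebraic identities and domain checks", {
  expect_equal(mm_rate(0, V_max = 2, K_M = 50), 0)
  expect_equal(mm_rate(50, V_max = 2, K_M = 50), 1)        # half saturation
  expect_equal(mm_rate(9 * 50, V_max = 2, K_M = 50), 1.8)  # 0.9 * V_max
  # monotone and bounded over a sweep
  S <- seq(0, 5000, length.out = 200)
  v <- mm_rate(S, V_max = 3, K_M = 120)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v <= 3))
  expect_error(mm_rate(-1, 1, 1), class = "gfetkin_domain_error")
  expect_error(mm_rate(NaN, 1, 1), class = "gfetkin_domain_error")
  expect_error(mm_rate(10, 0, 1), class = "gfetkin_domain_error")
  expect_error(mm_rate(10, 1, -5), class = "gfetkin_domain_error")
})

test_that("derived K_M and V_max come from the elementary constants", {
  p <- kinetic_params(k1 = 0.2, k2 = 6, k_cat = 14, E_total = 0.5)
  expect_equal(km(p), (6 + 14) / 0.2)
  expect_equal(vmax(p), 14 * 0.5)
  expect_error(kinetic_params(0, 1, 1, 1), class = "gfetkin_domain_error")
  expect_error(kinetic_params(1, 1, 1, -1), class = "gfetkin_domain_error")
})

test_that("MM trajectories conserve enzyme and substrate mass", {
  cases <- list(
    list(p = kinetic_params(1, 50, 100, 0.01), S0 = 250),
    list(p = kinetic_params(0.05, 2, 1, 0.3), S0 = 40),
    list(p = kinetic_params(10, 500, 20, 0.002), S0 = 800))
  for (cs in cases) {
    tr <- simulate_mm(cs$p, init = c(S = cs$S0), times = seq(0, 30, 0.25))
    tol <- 10 * attr(tr, "rtol") * max(cs$S0, 1)
    expect_lt(max(abs(tr$S + tr$C + tr$P - cs$S0)), tol)
    expect_lt(max(abs(tr$E + tr$C - cs$p$E_total)), tol)
    expect_true(all(diff(tr$P) >= -1e-10))
  }
})

test_that("with catalysis switched off the complex settles at the binding equilibrium", {
  # oracle: root of k1 (E_tot - C)(S_tot - C) = k2 C, the smaller root of
  # C^2 - (E_tot + S_tot + K_d) C + E_tot S_tot = 0
  p <- kinetic_params(k1 = 0.1, k2 = 2, k_cat = 0, E_total = 5)
  S0 <- 60
  Kd <- p$k2 / p$k1
  b <- p$E_total + S0 + Kd
  C_star <- (b - sqrt(b^2 - 4 * p$E_total * S0)) / 2
  tr <- simulate_mm(p, init = c(S = S0), times = c(0, 10^(0:3)))
  expect_equal(utils::tail(tr$C, 1), C_star, tolerance = 1e-6)
  expect_equal(utils::tail(tr$P, 1), 0)
})

test_that("a substrate-free system stays exactly constant", {
  p <- kinetic_params(1, 10, 5, 0.1)
  tr <- simulate_mm(p, init = c(S = 0), times = seq(0, 50, 1))
  expect_true(all(tr$S == 0))
  expect_true(all(tr$P == 0))
  expect_equal(tr$E, rep(0.1, nrow(tr)))
})

test_that("initial rates from the ODE match the closed-form MM rate under QSS", {
  # grid spanning a decade in K_M and k_cat, E_tot <= 0.01 S0, k1 S0 >= 100 k_cat
  grid <- expand.grid(K_M = c(30, 60, 120, 180, 300),
                      k_cat = c(2, 5, 10, 20))
  errs <- apply(grid, 1, function(g) {
    K_M <- g[["K_M"]]; k_cat <- g[["k_cat"]]
    S0 <- 100
    k1 <- max(1, 100 * k_cat / S0) * 2
    p <- kinetic_params(k1, k1 * K_M - k_cat, k_cat, 0.001 * S0)
    v_true <- mm_rate(S0, vmax(p), km(p))
    t_max <- 0.005 * S0 / v_true # cap product at ~0.5% of S0
    tr <- simulate_mm(p, init = c(S = S0), times = seq(0, t_max, length.out = 60))
    abs(initial_rate(tr, fraction = 0.2) / v_true - 1)
  })
  expect_gte(length(errs), 20)
  expect_lt(max(errs), 0.01)
})

test_that("initial_rate recovers exact lines and rejects deficient windows", {
  tl <- tibble::tibble(time_s = 0:19, P = 0.3 * (0:19))
  expect_equal(initial_rate(tl, fraction = 0.2, s0 = 1000), 0.3)
  flat <- tibble::tibble(time_s = 0:19, P = rep(1, 20))
  expect_equal(initial_rate(flat, s0 = 100), 0)
  expect_error(initial_rate(tl[1:4, ], s0 = 1000),
               class = "gfetkin_insufficient_data")
  # cutoff reached after 2 points -> insufficient window
  steep <- tibble::tibble(time_s = 0:9, P = c(0, 5, 40, 80, 80, 80, 80, 80, 80, 80))
  expect_error(initial_rate(steep, fraction = 0.1, s0 = 100),
               class = "gfetkin_insufficient_data")
  expect_error(initial_rate(tl, fraction = 0.5, s0 = 100),
               class = "gfetkin_domain_error")
})

test_that("peroxidase network conserves total enzyme and orders cosubstrate scenarios", {
  pp <- peroxidase_params()
  E0 <- 1
  runs <- lapply(c(75, 500), function(aa) {
    simulate_peroxidase(pp, init = c(E = E0, H2O2 = 50, AH2 = aa),
                        times = seq(0, 400, 2))
  })
  for (tr in runs) {
    tot <- tr$E + tr$CpdI + tr$CpdII + tr$CpdIII + tr$E_inact
    expect_lt(max(abs(tot - E0)), 1e-6)
    expect_true(all(diff(tr$E_inact) >= -1e-10))
    expect_true(all(diff(tr$Prod) >= -1e-10))
  }
  # sufficient cosubstrate protects the enzyme
  af <- vapply(runs, function(tr) utils::tail(active_fraction(tr), 1), 0)
  expect_gt(af[2], af[1])
})

test_that("bleaching switched off keeps the competent pool fully conserved", {
  pp <- peroxidase_params(k_p6 = 0)
  tr <- simulate_peroxidase(pp, init = c(E = 2, H2O2 = 100, AH2 = 50),
                            times = seq(0, 300, 2))
  expect_true(all(tr$E_inact == 0))
  expect_lt(max(abs(active_fraction(tr) - 1)), 1e-7)
})

test_that("reductant-free peroxide exposure inactivates the enzyme past half", {
  pp <- peroxidase_params()
  tr <- simulate_peroxidase(pp, init = c(E = 1, H2O2 = 50),
                            times = seq(0, 1200, 2))
  af <- active_fraction(tr)
  expect_true(all(diff(af) <= 1e-10))
  expect_lt(min(af), 0.5)
  # bisection on the dense grid for the crossing time, then check beyond it
  lo <- max(which(af >= 0.5)); hi <- min(which(af < 0.5))
  expect_equal(hi, lo + 1)
  expect_true(all(af[hi:length(af)] < 0.5))
})

test_that("with no peroxide-driven branches the cycle is ping-pong and linear in scarce AH2", {
  pp <- peroxidase_params(k_p5 = 0, k_p6 = 0, k_p1b = 0)
  rate_at <- function(aa) {
    tr <- simulate_peroxidase(pp, init = c(E = 0.05, H2O2 = 5000, AH2 = aa),
                              times = seq(0, 2, 0.02))
    initial_rate(tr, fraction = 0.05, product = "Prod", s0 = aa)
  }
  v1 <- rate_at(2); v2 <- rate_at(4)
  # doubling scarce cosubstrate doubles the product formation rate
  expect_equal(v2 / v1, 2, tolerance = 0.05)
})

test_that("identical inputs give bit-identical trajectories", {
  p <- kinetic_params(1, 50, 100, 0.01)
  a <- simulate_mm(p, init = c(S = 100), times = seq(0, 10, 0.1))
  b <- simulate_mm(p, init = c(S = 100), times = seq(0, 10, 0.1))
  expect_identical(a, b)
})

test_that("trajectories round-trip through tidy CSV", {
  p <- kinetic_params(1, 50, 100, 0.01)
  tr <- simulate_mm(p, init = c(S = 100), times = seq(0, 5, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(as.data.frame(back)[c("time_s", "S", "E", "C", "P")],
               as.data.frame(tr)[c("time_s", "S", "E", "C", "P")],
               tolerance = 1e-12)
})
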