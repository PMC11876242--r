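#' Michaelis-Menten kinetic parameters
#'
#' Bundles the elementary rate constants of the single-substrate catalytic
#' scheme `E + S <-> C -> E + P` together with the total enzyme
#' concentration. The Michaelis constant and limiting rate are always
#' derived from the elementary constants, never stored:
#' `K_M = (k2 + k_cat) / k1` and `V_max = k_cat * E_total`.
#'
#' @param k1 Association rate constant, 1/(uM s).
#' @param k2 Dissociation rate constant, 1/s.
#' @param k_cat Catalytic rate constant, 1/s.
#' @param E_total Total enzyme concentration, uM.
#' @return An object of class `kinetic_params`.
#' @seealso [km()], [vmax()], [simulate_mm()]
#' @export
#' @examples
#' p <- kinetic_params(k1 = 0.1, k2 = 5, k_cat = 10, E_total = 0.01)
#' km(p)    # (5 + 10) / 0.1 = 150 uM
#' vmax(p)  # 0.1 uM/s
kinetic_params <- function(k1, k2, k_cat, E_total) {
  check_scalar(k1, "k1", positive = TRUE)
  check_scalar(k2, "k2", positive = TRUE)
  # k_cat = 0 is the binding-only limit, useful for equilibrium checks
  check_scalar(k_cat, "k_cat", non_negative = TRUE)
  check_scalar(E_total, "E_total", positive = TRUE)
  structure(list(k1 = k1, k2 = k2, k_cat = k_cat, E_total = E_total),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Michaelis-Menten kinetic parameters\n")
  cat(sprintf("  k1 = %g 1/(uM s), k2 = %g 1/s, k_cat = %g 1/s, E_total = %g uM\n",
              x$k1, x$k2, x$k_cat, x$E_total))
  cat(sprintf("  derived: K_M = %g uM, V_max = %g uM/s\n", km(x), vmax(x)))
  invisible(x)
}

#' Derived Michaelis constant (uM)
#' @param params A [kinetic_params()] object.
#' @return `(k2 + k_cat) / k1` in uM.
#' @export
km <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  (params$k2 + params$k_cat) / params$k1
}

#' Derived limiting rate (uM/s)
#' @param params A [kinetic_params()] object.
#' @return `k_cat * E_total` in uM/s.
#' @export
vmax <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k_cat * params$E_total
}

#' Closed-form Michaelis-Menten rate
#'
#' The hyperbolic rate law `v = V_max * S / (K_M + S)` relating initial
#' reaction velocity to substrate concentration.
#'
#' @param S Substrate concentration(s), uM. Vectorised.
#' @param V_max Limiting rate, uM/s.
#' @param K_M Michaelis constant, uM.
#' @return Reaction rate(s), uM/s. Monotone non-decreasing in `S`, bounded
#'   above by `V_max`.
#' @export
#' @examples
#' mm_rate(150, V_max = 1, K_M = 150) # half-saturation: 0.5
mm_rate <- function(S, V_max, K_M) {
  if (!is.numeric(S) || length(S) < 1L || anyNA(S) || any(!is.finite(S)) ||
      any(S < 0)) {
    abort("`S` must be finite and non-negative.", class = "gfetkin_domain_error")
  }
  check_scalar(V_max, "V_max", positive = TRUE)
  check_scalar(K_M, "K_M", positive = TRUE)
  V_max * S / (K_M + S)
}

new_trajectory <- function(df, kind, params, rtol, atol) {
  out <- as_tibble(df)
  # solver round-off can leave tiny negative concentrations; clamp on output
  num <- setdiff(names(out), "time_s")
  for (nm in num) out[[nm]] <- pmax(out[[nm]], 0)
  attr(out, "kind") <- kind
  attr(out, "params") <- params
  attr(out, "rtol") <- rtol
  attr(out, "atol") <- atol
  class(out) <- c("kin_trajectory", class(out))
  out
}

integrate_ode <- function(y0, times, rhs, parms, rtol, atol) {
  sol <- deSolve::lsoda(y = y0, times = times, func = rhs, parms = parms,
                        rtol = rtol, atol = atol)
  diagn <- attributes(sol)$istate
  if (!is.null(diagn) && diagn[1] < 0) {
    abort(sprintf("ODE integration failed (lsoda istate = %d).", diagn[1]),
          class = "gfetkin_integration_error")
  }
  df <- as.data.frame(sol)
  names(df)[1] <- "time_s"
  df
}

#' Simulate the Michaelis-Menten ODE system
#'
#' Integrates the mass-action equations of `E + S <-> C -> E + P`:
#' \deqn{dS/dt = -k_1 E S + k_2 C,\quad dC/dt = k_1 E S - (k_2+k_{cat}) C,}
#' \deqn{dE/dt = -dC/dt,\quad dP/dt = k_{cat} C.}
#' Enzyme (`E + C`) and substrate mass (`S + C + P`) are conserved; the
#' stiff solver tolerances default tight enough that conservation holds to
#' ~`10 * rtol` at all output times.
#'
#' @param params A [kinetic_params()] object.
#' @param init Named numeric vector with entries `S`, `E`, `C`, `P` (uM).
#'   Defaults: `E = E_total`, `C = 0`, `P = 0`. Must satisfy
#'   `E + C == E_total`.
#' @param times Strictly increasing time grid, seconds, starting at 0.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A `kin_trajectory` tibble with columns `time_s, S, E, C, P`.
#' @export
#' @examples
#' p <- kinetic_params(0.1, 5, 10, 0.01)
#' tr <- simulate_mm(p, init = c(S = 100), times = seq(0, 20, by = 0.5))
#' head(tr)
simulate_mm <- function(params, init = c(S = 100), times = seq(0, 60, by = 0.5),
                        rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"))
  check_times(times)
  if (times[1] != 0) {
    abort("`times` must start at 0.", class = "gfetkin_domain_error")
  }
  y0 <- c(S = NA_real_, E = params$E_total, C = 0, P = 0)
  y0[names(init)] <- init
  if (anyNA(y0)) {
    abort("`init` must provide at least `S`.", class = "gfetkin_domain_error")
  }
  if (any(y0 < 0)) {
    abort("Initial concentrations must be non-negative.",
          class = "gfetkin_domain_error")
  }
  if (abs(y0[["E"]] + y0[["C"]] - params$E_total) > 1e-8 * max(1, params$E_total)) {
    abort("`init` violates enzyme conservation: E + C must equal E_total.",
          class = "gfetkin_domain_error")
  }
  rhs <- function(t, y, p) {
    bind_f <- p$k1 * y[["E"]] * y[["S"]]
    unbind <- p$k2 * y[["C"]]
    catal <- p$k_cat * y[["C"]]
    list(c(S = -bind_f + unbind,
           E = -bind_f + unbind + catal,
           C = bind_f - unbind - catal,
           P = catal))
  }
  df <- integrate_ode(y0, times, rhs, params, rtol, atol)
  new_trajectory(df, "mm", params, rtol, atol)
}

#' Peroxidase catalytic-network rate constants
#'
#' Rate constants of the heme-peroxidase catalytic cycle with
#' peroxide-driven suicide inactivation. Pathways: (1) resting enzyme +
#' H2O2 forms compound I; (2) compound I oxidises one reducing-cosubstrate
#' molecule (AH2) to product, forming compound II; (3) compound II oxidises
#' a second AH2, returning the resting enzyme; (5) compound II + H2O2 forms
#' the off-pathway compound III; (6) compound III bleaches irreversibly to
#' inactive enzyme. An optional slow first-order decay of compound III back
#' to the resting state (`k_p4`, default 0) is included for completeness.
#'
#' With the five pathways alone, a run with no reducing cosubstrate at all
#' would park the entire enzyme pool as compound I and never bleach —
#' whereas reductant-free peroxide exposure is precisely the condition
#' under which heme bleaching is observed experimentally. The established
#' catalase-like side reaction CpdI + H2O2 -> CpdII (`k_p1b`) supplies
#' that reductant-free route into compounds II and III and is part of the
#' default network; set `k_p1b = 0` to recover the bare five-pathway
#' cycle.
#'
#' @param k_p1 E + H2O2 -> CpdI, 1/(uM s). Must be > 0.
#' @param k_p2 CpdI + AH2 -> CpdII + Prod, 1/(uM s).
#' @param k_p3 CpdII + AH2 -> E + Prod, 1/(uM s).
#' @param k_p5 CpdII + H2O2 -> CpdIII, 1/(uM s).
#' @param k_p6 CpdIII -> inactive enzyme (bleaching), 1/s.
#' @param k_p4 CpdIII -> E slow recovery, 1/s (default 0).
#' @param k_p1b CpdI + H2O2 -> CpdII (catalase-like, reductant-free),
#'   1/(uM s).
#' @return An object of class `peroxidase_params`.
#' @export
peroxidase_params <- function(k_p1 = 1e-2, k_p2 = 1e-2, k_p3 = 5e-3,
                              k_p5 = 1e-3, k_p6 = 5e-3, k_p4 = 0,
                              k_p1b = 2e-3) {
  check_scalar(k_p1, "k_p1", positive = TRUE)
  for (nm in c("k_p2", "k_p3", "k_p5", "k_p6", "k_p4", "k_p1b")) {
    check_scalar(get(nm), nm, non_negative = TRUE)
  }
  structure(list(k_p1 = k_p1, k_p2 = k_p2, k_p3 = k_p3,
                 k_p5 = k_p5, k_p6 = k_p6, k_p4 = k_p4, k_p1b = k_p1b),
            class = "peroxidase_params")
}

#' @export
print.peroxidase_params <- function(x, ...) {
  cat("Peroxidase network rate constants (pathways 1,2,3,5,6; optional 4; catalase-like 1b)\n")
  cat(sprintf("  k_p1=%g k_p1b=%g k_p2=%g k_p3=%g k_p5=%g [1/(uM s)]  k_p6=%g k_p4=%g [1/s]\n",
              x$k_p1, x$k_p1b, x$k_p2, x$k_p3, x$k_p5, x$k_p6, x$k_p4))
  invisible(x)
}

#' Simulate the peroxidase catalytic network with suicide inactivation
#'
#' Integrates one mass-action term per pathway of the catalytic cycle (see
#' [peroxidase_params()]). Pathways 2 and 3 each consume one AH2 and
#' produce one oxidised product molecule. The sum of the five enzyme
#' species (`E + CpdI + CpdII + CpdIII + E_inact`) is conserved; with
#' bleaching switched off (`k_p6 = 0`) the catalytically competent pool is
#' itself conserved. `E_inact` and `Prod` are non-decreasing.
#'
#' @param params A [peroxidase_params()] object.
#' @param init Named numeric vector over
#'   `E, CpdI, CpdII, CpdIII, E_inact, H2O2, AH2, Prod` (uM). Unnamed
#'   species default to 0.
#' @param times Strictly increasing time grid, seconds, starting at 0.
#' @param rtol,atol Solver tolerances.
#' @return A `kin_trajectory` tibble with one column per species.
#' @export
#' @examples
#' pp <- peroxidase_params()
#' tr <- simulate_peroxidase(pp, init = c(E = 1, H2O2 = 50, AH2 = 500),
#'                           times = seq(0, 100, by = 1))
#' active_fraction(tr)[c(1, 101)]
simulate_peroxidase <- function(params, init, times = seq(0, 300, by = 1),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "peroxidase_params"))
  check_times(times)
  if (times[1] != 0) {
    abort("`times` must start at 0.", class = "gfetkin_domain_error")
  }
  species <- c("E", "CpdI", "CpdII", "CpdIII", "E_inact", "H2O2", "AH2", "Prod")
  y0 <- setNames(rep(0, length(species)), species)
  bad <- setdiff(names(init), species)
  if (length(bad)) {
    abort(paste0("Unknown species in `init`: ", paste(bad, collapse = ", ")),
          class = "gfetkin_domain_error")
  }
  y0[names(init)] <- init
  if (any(y0 < 0)) {
    abort("Initial concentrations must be non-negative.",
          class = "gfetkin_domain_error")
  }
  rhs <- function(t, y, p) {
    r1 <- p$k_p1 * y[["E"]] * y[["H2O2"]]
    r1b <- p$k_p1b * y[["CpdI"]] * y[["H2O2"]]
    r2 <- p$k_p2 * y[["CpdI"]] * y[["AH2"]]
    r3 <- p$k_p3 * y[["CpdII"]] * y[["AH2"]]
    r5 <- p$k_p5 * y[["CpdII"]] * y[["H2O2"]]
    r6 <- p$k_p6 * y[["CpdIII"]]
    r4 <- p$k_p4 * y[["CpdIII"]]
    list(c(E = -r1 + r3 + r4,
           CpdI = r1 - r2 - r1b,
           CpdII = r2 + r1b - r3 - r5,
           CpdIII = r5 - r6 - r4,
           E_inact = r6,
           H2O2 = -r1 - r5 - r1b,
           AH2 = -r2 - r3,
           Prod = r2 + r3))
  }
  df <- integrate_ode(y0, times, rhs, params, rtol, atol)
  new_trajectory(df, "peroxidase", params, rtol, atol)
}

#' Catalytically active enzyme fraction along a peroxidase trajectory
#'
#' @param traj A peroxidase `kin_trajectory`.
#' @return Numeric vector, `(E + CpdI + CpdII + CpdIII) / E_total` at each
#'   output time; `E_total` is the (conserved) sum of all five enzyme
#'   species at t = 0.
#' @export
active_fraction <- function(traj) {
  stopifnot(inherits(traj, "kin_trajectory"),
            identical(attr(traj, "kind"), "peroxidase"))
  tot <- traj$E[1] + traj$CpdI[1] + traj$CpdII[1] + traj$CpdIII[1] +
    traj$E_inact[1]
  if (tot <= 0) abort("Trajectory has no enzyme.", class = "gfetkin_domain_error")
  (traj$E + traj$CpdI + traj$CpdII + traj$CpdIII) / tot
}

#' Initial-rate extraction from a progress curve
#'
#' Ordinary-least-squares slope of product versus time over the earliest
#' portion of a progress curve, the standard initial-velocity estimate used
#' to build rate-versus-substrate datasets. The window comprises the
#' earliest points at which accumulated product is below
#' `fraction * S0` (substrate depletion still negligible).
#'
#' @param traj A `kin_trajectory` or any data frame with a time column and
#'   a product column.
#' @param fraction Depletion cutoff defining the fitting window; must lie
#'   in `(0, 0.2]`. Default 0.1.
#' @param product Name of the product column (default `"P"`; use
#'   `"Prod"` for peroxidase trajectories, `"conc_uM"` for recovered GFET
#'   series).
#' @param time Name of the time column (default `"time_s"`).
#' @param s0 Initial substrate concentration, uM. Defaults to
#'   `S + C + P` at the first time point when those columns exist.
#' @return Initial rate `v0` in uM/s (a single number).
#' @export
initial_rate <- function(traj, fraction = 0.1, product = "P",
                         time = "time_s", s0 = NULL) {
  df <- as.data.frame(traj)
  if (nrow(df) < 5L) {
    abort("Need at least 5 trajectory points.", class = "gfetkin_insufficient_data")
  }
  check_scalar(fraction, "fraction", positive = TRUE)
  if (fraction > 0.2) {
    abort("`fraction` must be at most 0.2.", class = "gfetkin_domain_error")
  }
  if (!all(c(time, product) %in% names(df))) {
    abort("Trajectory lacks the requested time/product columns.",
          class = "gfetkin_domain_error")
  }
  if (is.null(s0)) {
    if (all(c("S", "C", "P") %in% names(df))) {
      s0 <- df$S[1] + df$C[1] + df$P[1]
    } else {
      abort("`s0` must be supplied when the trajectory carries no substrate columns.",
            class = "gfetkin_domain_error")
    }
  }
  check_scalar(s0, "s0", positive = TRUE)
  p <- df[[product]]
  keep <- p < fraction * s0
  # earliest contiguous run only: stop at the first point past the cutoff
  past <- which(!keep)
  if (length(past)) keep[seq_along(keep) >= past[1]] <- FALSE
  if (sum(keep) < 3L) {
    abort("Fewer than 3 points below the depletion cutoff; cannot fit an initial rate.",
          class = "gfetkin_insufficient_data")
  }
  fit <- lm(p[keep] ~ df[[time]][keep])
  unname(coef(fit)[2])
}
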