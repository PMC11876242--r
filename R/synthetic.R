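#' Ground-truth parameter law across chemical and environmental conditions
#'
#' Smooth law mapping assay conditions to true Michaelis-Menten parameters,
#' used as the synthetic study's ground truth. Temperature acts on the
#' turnover number through an Arrhenius-like exponential around a reference
#' temperature; pH acts through a Gaussian activity profile centred on the
#' enzyme's optimum (turnover) and a log-linear shift (Michaelis constant):
#' \deqn{k_{cat} = k_{cat,ref}\, e^{E_a (T - T_{ref})}\,
#'   e^{-((pH - pH_{opt})/w)^2},\qquad
#'   K_M = K_{M,ref}\, e^{s (pH - pH_{opt})}.}
#'
#' Defaults are literature-plausible magnitudes for heme peroxidases with
#' ABTS as cosubstrate; they are synthetic ground truth, not measured
#' values. The pH optimum is enzyme-specific: 7 for HRP, 4 for free heme.
#'
#' @param kcat_ref Turnover number at the reference condition, 1/s.
#' @param K_M_ref Michaelis constant at the reference condition, uM.
#' @param Ea_like Temperature sensitivity of the turnover, per K.
#' @param pH_width Width of the Gaussian pH-activity profile, pH units.
#' @param K_M_pH_slope Log-linear pH sensitivity of K_M, per pH unit.
#' @param T_ref Reference temperature, degrees C.
#' @param pH_opt Named numeric, optimal pH per enzyme.
#' @return An object of class `ground_truth_law`.
#' @export
ground_truth_law <- function(kcat_ref = 100, K_M_ref = 150, Ea_like = 0.08,
                             pH_width = 2, K_M_pH_slope = 0.4, T_ref = 22,
                             pH_opt = c(HRP = 7, heme = 4)) {
  check_scalar(kcat_ref, "kcat_ref", positive = TRUE)
  check_scalar(K_M_ref, "K_M_ref", positive = TRUE)
  check_scalar(Ea_like, "Ea_like")
  check_scalar(pH_width, "pH_width", positive = TRUE)
  check_scalar(K_M_pH_slope, "K_M_pH_slope")
  check_scalar(T_ref, "T_ref")
  stopifnot(is.numeric(pH_opt), !is.null(names(pH_opt)))
  structure(list(kcat_ref = kcat_ref, K_M_ref = K_M_ref, Ea_like = Ea_like,
                 pH_width = pH_width, K_M_pH_slope = K_M_pH_slope,
                 T_ref = T_ref, pH_opt = pH_opt),
            class = "ground_truth_law")
}

#' Evaluate the ground-truth law at experimental conditions
#'
#' @param law A [ground_truth_law()].
#' @param conditions Data frame with columns `enzyme`, `pH`,
#'   `temperature_C` (extra columns are carried through untouched).
#' @return The input as a tibble with columns `K_M_true` (uM) and
#'   `kcat_true` (1/s) appended. Deterministic.
#' @export
#' @examples
#' law <- ground_truth_law()
#' ground_truth(law, tibble::tibble(enzyme = "HRP", pH = 7, temperature_C = 22))
ground_truth <- function(law, conditions) {
  stopifnot(inherits(law, "ground_truth_law"))
  df <- as_tibble(conditions)
  need <- c("enzyme", "pH", "temperature_C")
  if (!all(need %in% names(df))) {
    abort("`conditions` must carry enzyme, pH and temperature_C columns.",
          class = "gfetkin_domain_error")
  }
  if (!all(df$enzyme %in% names(law$pH_opt))) {
    abort("Condition enzyme not covered by the law's pH optima.",
          class = "gfetkin_domain_error")
  }
  opt <- unname(law$pH_opt[df$enzyme])
  df$kcat_true <- law$kcat_ref *
    exp(law$Ea_like * (df$temperature_C - law$T_ref)) *
    exp(-((df$pH - opt) / law$pH_width)^2)
  df$K_M_true <- law$K_M_ref * exp(law$K_M_pH_slope * (df$pH - opt))
  df
}

#' Default synthetic condition grid
#'
#' Enumerates the experimental design emulated by the synthetic study:
#' two enzymes (HRP and free heme), two pH values (4 and 7), temperatures
#' spanning 18-25 degrees C, and the standard seven-point ABTS substrate
#' series 25-1000 uM measured at constant gate/drain voltage with the
#' peroxide cosubstrate in excess. One replicate reference series per
#' enzyme at 22 degrees C and its optimal pH is appended, giving 98
#' conditions in total. Each condition is one substrate concentration;
#' conditions sharing `group_id` form one rate-versus-substrate series.
#'
#' @param enzymes Character vector of enzymes.
#' @param pH Numeric vector of pH values.
#' @param temperatures_C Numeric vector of temperatures, degrees C.
#' @param substrate_series Substrate concentrations, uM.
#' @param reference_T Temperature of the appended replicate series.
#' @return Tibble with one row per condition: `condition_id`, `group_id`,
#'   `enzyme`, `pH`, `temperature_C`, `substrate`, `substrate_conc_uM`,
#'   `cosubstrate_conc_uM`, `V_g_mV`, `V_ds_mV`, `replicate`.
#' @export
default_condition_grid <- function(enzymes = c("HRP", "heme"),
                                   pH = c(4, 7),
                                   temperatures_C = c(18, 21, 24),
                                   substrate_series = c(25, 50, 100, 250, 500,
                                                        750, 1000),
                                   reference_T = 22) {
  stopifnot(all(pH >= 0), all(temperatures_C >= 18 - 1e-9),
            all(temperatures_C <= 25 + 1e-9),
            all(substrate_series >= 25), all(substrate_series <= 1000))
  base <- tidyr::expand_grid(enzyme = enzymes, pH = pH,
                             temperature_C = temperatures_C,
                             replicate = 1L,
                             substrate_conc_uM = substrate_series)
  pH_opt <- c(HRP = 7, heme = 4)
  ref <- tidyr::expand_grid(enzyme = enzymes,
                            substrate_conc_uM = substrate_series) |>
    mutate(pH = unname(pH_opt[.data$enzyme]),
           temperature_C = reference_T, replicate = 2L)
  grid <- bind_rows(base, ref) |>
    mutate(substrate = "ABTS",
           cosubstrate_conc_uM = 2500, # H2O2 in excess (2.5 mM)
           V_g_mV = ifelse(.data$enzyme == "HRP", 500, 100),
           V_ds_mV = 500,
           group_id = sprintf("%s_pH%g_T%g_r%d", .data$enzyme, .data$pH,
                              .data$temperature_C, .data$replicate)) |>
    mutate(condition_id = sprintf("%s_S%04d", .data$group_id,
                                  as.integer(.data$substrate_conc_uM))) |>
    select("condition_id", "group_id", "enzyme", "pH", "temperature_C",
           "substrate", "substrate_conc_uM", "cosubstrate_conc_uM",
           "V_g_mV", "V_ds_mV", "replicate")
  grid
}

#' Generate a complete synthetic GFET kinetics study
#'
#' For every condition in the grid: evaluate the ground-truth law, simulate
#' the Michaelis-Menten progress curve (cosubstrate in excess, so
#' single-substrate kinetics applies), and pass the product series through
#' the forward sensor model to obtain a noisy constant-voltage current
#' trace. Per-condition seeds are derived from `master_seed` and the
#' condition id, so regeneration is bit-identical and order-independent.
#'
#' @param law A [ground_truth_law()].
#' @param grid Condition tibble, as from [default_condition_grid()].
#' @param cal A `calibration_model` used as the sensor's ground truth.
#' @param noise_sd Trace noise standard deviation, uA.
#' @param master_seed Integer master seed.
#' @param E_total Total enzyme concentration, uM.
#' @param k1 Association rate constant, 1/(uM s) (with the law's K_M and
#'   k_cat this fixes k2 = k1 * K_M - k_cat, which must stay positive).
#' @param times Trace time grid, seconds.
#' @return An object of class `experiment_set`: list with `conditions`
#'   (grid + true parameters), `traces` (one `current_trace` tibble,
#'   row-bound, one trace per condition), `truth` (condition_id, K_M_true,
#'   kcat_true), and the generation settings.
#' @export
generate_experiment_set <- function(law, grid = default_condition_grid(),
                                    cal = calibration_model(slope = 2),
                                    noise_sd = 0.1, master_seed = 1,
                                    E_total = 0.01, k1 = 1,
                                    times = seq(0, 60, by = 0.5)) {
  stopifnot(inherits(law, "ground_truth_law"), inherits(cal, "calibration_model"))
  conditions <- ground_truth(law, grid)
  if (anyDuplicated(conditions$condition_id)) {
    abort("Condition ids must be unique.", class = "gfetkin_domain_error")
  }
  traces <- purrr::pmap(conditions, function(condition_id, enzyme, pH,
                                             temperature_C, substrate_conc_uM,
                                             V_g_mV, V_ds_mV, K_M_true,
                                             kcat_true, ...) {
    k2 <- k1 * K_M_true - kcat_true
    if (k2 <= 0) {
      abort(sprintf("Condition %s: k1 * K_M <= k_cat; raise `k1`.", condition_id),
            class = "gfetkin_domain_error")
    }
    p <- kinetic_params(k1 = k1, k2 = k2, k_cat = kcat_true, E_total = E_total)
    traj <- simulate_mm(p, init = c(S = substrate_conc_uM), times = times)
    concentration_to_current(
      tibble(time_s = traj$time_s, conc_uM = traj$P), cal,
      noise_sd = noise_sd,
      seed = derive_seed(master_seed, condition_id),
      V_g_mV = V_g_mV, V_ds_mV = V_ds_mV, condition_id = condition_id)
  })
  structure(list(conditions = conditions,
                 traces = bind_rows(traces),
                 truth = select(conditions, "condition_id", "group_id",
                                "K_M_true", "kcat_true"),
                 cal = cal, law = law, noise_sd = noise_sd,
                 master_seed = master_seed, E_total = E_total, k1 = k1),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf("Synthetic GFET kinetics study: %d conditions in %d substrate series\n",
              nrow(x$conditions), length(unique(x$conditions$group_id))))
  cat(sprintf("  enzymes: %s | pH: %s | T: %s C\n",
              paste(unique(x$conditions$enzyme), collapse = ", "),
              paste(sort(unique(x$conditions$pH)), collapse = ", "),
              paste(sort(unique(x$conditions$temperature_C)), collapse = ", ")))
  cat(sprintf("  trace noise sd = %g uA, master seed = %d\n",
              x$noise_sd, as.integer(x$master_seed)))
  invisible(x)
}

#' Extract rate-versus-substrate datasets from an experiment set
#'
#' Recovers product concentration from each trace through the calibration
#' model, extracts the initial rate, and assembles one
#' rate-versus-substrate table per condition group (one substrate series).
#'
#' When the fitted calibration carries a positive intercept, samples whose
#' current change falls below it invert to exactly zero concentration:
#' they are left-censored by the sensor map, not real observations, so
#' they are excluded from the slope fit (a constant concentration offset
#' cancels in the slope; censored zeros do not). A trace with too few
#' uncensored samples is reported as below the detection limit
#' (`v0 = 0`).
#'
#' @param expset An `experiment_set`.
#' @param cal Calibration model used for trace inversion (defaults to the
#'   set's own sensor model).
#' @param fraction Depletion cutoff passed to [initial_rate()].
#' @return Tibble with columns `condition_id`, `group_id`, `S_uM`,
#'   `v0_uM_per_s`.
#' @export
extract_rates <- function(expset, cal = expset$cal, fraction = 0.1) {
  stopifnot(inherits(expset, "experiment_set"))
  conds <- expset$conditions
  rates <- purrr::map_dbl(seq_len(nrow(conds)), function(i) {
    tr <- filter(expset$traces, .data$condition_id == conds$condition_id[i])
    conc <- current_to_concentration(tr, cal)
    usable <- filter(conc, .data$conc_uM > 0)
    if (nrow(usable) < 5L) return(0) # below detection limit
    tryCatch(
      initial_rate(usable, fraction = fraction, product = "conc_uM",
                   s0 = conds$substrate_conc_uM[i]),
      gfetkin_insufficient_data = function(e) 0)
  })
  tibble(condition_id = conds$condition_id, group_id = conds$group_id,
         S_uM = conds$substrate_conc_uM, v0_uM_per_s = pmax(rates, 0))
}

#' Peroxidase suicide-inactivation scenarios at varying cosubstrate
#'
#' Simulates the peroxidase catalytic network at a fixed peroxide
#' challenge across a series of reducing-cosubstrate (e.g. ascorbic acid)
#' concentrations, the classic "sufficient" (500 uM) versus "insufficient"
#' (75 uM) design that exposes peroxide-driven bleaching: with little
#' cosubstrate the enzyme accumulates as compound III and inactivates,
#' with ample cosubstrate the cycle turns over and the enzyme survives.
#'
#' @param params A [peroxidase_params()].
#' @param aa_levels Cosubstrate concentrations to test, uM.
#' @param h2o2 Peroxide concentration, uM.
#' @param E0 Enzyme concentration, uM.
#' @param times Time grid, seconds.
#' @return A tibble of class `inactivation_scenarios` with one row per
#'   cosubstrate level: `AH2_uM`, `final_active_fraction`, and a
#'   list-column `trajectory` of full network trajectories.
#' @export
generate_inactivation_scenarios <- function(params, aa_levels = c(0, 75, 500),
                                            h2o2 = 50, E0 = 1,
                                            times = seq(0, 600, by = 2)) {
  stopifnot(inherits(params, "peroxidase_params"))
  if (any(aa_levels < 0)) {
    abort("`aa_levels` must be non-negative.", class = "gfetkin_domain_error")
  }
  check_scalar(h2o2, "h2o2", non_negative = TRUE)
  runs <- purrr::map(aa_levels, function(aa) {
    simulate_peroxidase(params, init = c(E = E0, H2O2 = h2o2, AH2 = aa),
                        times = times)
  })
  out <- tibble(AH2_uM = aa_levels,
                final_active_fraction =
                  purrr::map_dbl(runs, ~ utils::tail(active_fraction(.x), 1)),
                trajectory = runs)
  class(out) <- c("inactivation_scenarios", class(out))
  out
}
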