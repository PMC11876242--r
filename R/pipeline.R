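#' Pipeline configuration
#'
#' Schema-validated configuration for [run_pipeline()]. A single
#' `master_seed` fans out to every stochastic stage through labelled seed
#' derivation ([derive_seed()]), so one number reproduces the whole study.
#' Unknown keys are rejected.
#'
#' @param master_seed Integer master seed.
#' @param out_dir Output directory for all artifacts.
#' @param stages Named logical vector toggling the stages
#'   `simulate, calibrate, rates, invert, train, diagnostics`. Later
#'   stages require the earlier ones.
#' @param law List of [ground_truth_law()] arguments.
#' @param grid List of [default_condition_grid()] arguments.
#' @param sensor List: `slope`, `intercept`, `linear_range`, `baseline_uA`,
#'   `noise_sd` (trace noise, uA) for the ground-truth transducer.
#' @param calibration List: `concs_uM` (calibration series),
#'   `rel_noise` (relative measurement noise of the calibration points),
#'   `r2_min` (linear-range detection threshold).
#' @param mcmc List: `n_chains`, `n_steps`, `burn_in`.
#' @param surrogate List of [train_surrogate()] tuning arguments
#'   (`hidden_sizes`, `lr`, `lr_decay`, `epochs`, `batch`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1,
                            out_dir = tempfile("gfetkin_run_"),
                            stages = c(simulate = TRUE, calibrate = TRUE,
                                       rates = TRUE, invert = TRUE,
                                       train = TRUE, diagnostics = TRUE),
                            law = list(),
                            grid = list(),
                            sensor = list(slope = 2, intercept = 0,
                                          linear_range = c(10, 70),
                                          baseline_uA = 10, noise_sd = 0.1),
                            calibration = list(concs_uM = seq(10, 120, by = 10),
                                               rel_noise = 0.02,
                                               n_replicates = 3,
                                               r2_min = 0.999),
                            mcmc = list(n_chains = 2, n_steps = 4000,
                                        burn_in = 2000),
                            surrogate = list(hidden_sizes = 16,
                                             lr = 0.01, lr_decay = 0.99,
                                             epochs = 800, batch = 32,
                                             weight_decay = 1e-4)) {
  check_scalar(master_seed, "master_seed")
  stage_names <- c("simulate", "calibrate", "rates", "invert", "train",
                   "diagnostics")
  full <- setNames(rep(FALSE, length(stage_names)), stage_names)
  bad <- setdiff(names(stages), stage_names)
  if (length(bad)) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")),
          class = "gfetkin_config_error")
  }
  full[names(stages)] <- stages
  check_keys <- function(lst, allowed, name) {
    extra <- setdiff(names(lst), allowed)
    if (length(extra)) {
      abort(sprintf("Unknown key(s) in `%s`: %s", name,
                    paste(extra, collapse = ", ")),
            class = "gfetkin_config_error")
    }
    lst
  }
  check_keys(law, names(formals(ground_truth_law)), "law")
  check_keys(grid, names(formals(default_condition_grid)), "grid")
  check_keys(sensor, c("slope", "intercept", "linear_range", "baseline_uA",
                       "noise_sd"), "sensor")
  check_keys(calibration, c("concs_uM", "rel_noise", "n_replicates", "r2_min"),
             "calibration")
  check_keys(mcmc, c("n_chains", "n_steps", "burn_in"), "mcmc")
  check_keys(surrogate, c("hidden_sizes", "lr", "lr_decay", "epochs", "batch",
                          "weight_decay"), "surrogate")
  defaults <- formals(pipeline_config)
  fill <- function(given, default) utils::modifyList(eval(default), given)
  structure(list(master_seed = as.integer(master_seed), out_dir = out_dir,
                 stages = full,
                 law = given_or(law), grid = given_or(grid),
                 sensor = fill(sensor, defaults$sensor),
                 calibration = fill(calibration, defaults$calibration),
                 mcmc = fill(mcmc, defaults$mcmc),
                 surrogate = fill(surrogate, defaults$surrogate)),
            class = "pipeline_config")
}

given_or <- function(x) if (length(x)) x else list()

#' Run the full synthetic-study pipeline
#'
#' Executes, in order: synthetic-study generation, calibration-curve
#' fitting, initial-rate extraction, per-series Bayesian inversion,
#' surrogate training, and diagnostics. Every artifact is written under
#' `config$out_dir` and listed in a manifest with its MD5 content hash;
#' rerunning with the same configuration reproduces every artifact
#' hash-identically.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `run_report`: list with `config`, `manifest` (tibble
#'   `file, md5`), and the stage outputs that ran (`expset`, `cal`,
#'   `rates`, `posteriors`, `surrogate`, `training_report`, `diagnostics`,
#'   `triplets` with per-condition truth / posterior median / surrogate
#'   prediction).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- list(config = config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(path) files <<- c(files, path)
  seed <- config$master_seed
  stage <- function(name) isTRUE(config$stages[[name]])
  current <- "setup"
  withCallingHandlers({
    truth_cal <- calibration_model(slope = config$sensor$slope,
                                   intercept = config$sensor$intercept,
                                   linear_range = config$sensor$linear_range)

    if (stage("simulate")) {
      current <- "simulate"
      say("simulate: generating synthetic study")
      law <- do.call(ground_truth_law, config$law)
      grid <- do.call(default_condition_grid, config$grid)
      out$expset <- generate_experiment_set(
        law, grid, cal = truth_cal, noise_sd = config$sensor$noise_sd,
        master_seed = derive_seed(seed, "simulate"))
      readr::write_csv(out$expset$conditions,
                       f <- file.path(config$out_dir, "conditions.csv"))
      emit(f)
      readr::write_csv(out$expset$traces,
                       f <- file.path(config$out_dir, "traces.csv"))
      emit(f)
      readr::write_csv(out$expset$truth,
                       f <- file.path(config$out_dir, "truth.csv"))
      emit(f)
    }

    if (stage("calibrate")) {
      current <- "calibrate"
      say("calibrate: fitting calibration curve")
      concs <- config$calibration$concs_uM
      # synthetic calibration measurements through the truth transducer:
      # each concentration measured in replicate at proportional noise,
      # replicate means fitted (the standard calibration protocol)
      resp <- abs(config$sensor$slope) * saturate_conc(
        concs, truth_cal$linear_range[["high"]]) + config$sensor$intercept
      nrep <- config$calibration$n_replicates
      meas <- with_seed(derive_seed(seed, "calibrate"), {
        draws <- matrix(rnorm(nrep * length(concs), rep(resp, each = nrep),
                              config$calibration$rel_noise *
                                rep(resp, each = nrep)),
                        nrow = nrep)
        colMeans(draws)
      })
      cal_tbl <- tibble(conc_uM = concs, delta_I_uA = meas)
      readr::write_csv(cal_tbl,
                       f <- file.path(config$out_dir, "calibration_points.csv"))
      emit(f)
      out$cal <- fit_calibration(cal_tbl, r2_min = config$calibration$r2_min)
      write_calibration(out$cal,
                        f <- file.path(config$out_dir, "calibration.json"))
      emit(f)
    }

    if (stage("rates")) {
      current <- "rates"
      if (is.null(out$expset) || is.null(out$cal)) {
        abort("`rates` requires the simulate and calibrate stages.",
              class = "gfetkin_config_error")
      }
      say("rates: extracting initial rates")
      out$rates <- extract_rates(out$expset, cal = out$cal)
      readr::write_csv(out$rates, f <- file.path(config$out_dir, "rates.csv"))
      emit(f)
    }

    if (stage("invert")) {
      current <- "invert"
      if (is.null(out$rates)) {
        abort("`invert` requires the rates stage.", class = "gfetkin_config_error")
      }
      groups <- unique(out$rates$group_id)
      say("invert: MCMC over %d substrate series", length(groups))
      out$posteriors <- setNames(lapply(groups, function(g) {
        d <- filter(out$rates, .data$group_id == g)
        ds <- rate_dataset(d$S_uM, d$v0_uM_per_s,
                           E_total = out$expset$E_total,
                           condition = list(group_id = g))
        run_mcmc(ds, n_chains = config$mcmc$n_chains,
                 n_steps = config$mcmc$n_steps,
                 burn_in = config$mcmc$burn_in,
                 seed = derive_seed(seed, paste0("invert_", g)))
      }), groups)
      summaries <- bind_rows(lapply(groups, function(g) {
        mutate(summarize_posterior(out$posteriors[[g]]), group_id = g,
               .before = 1)
      }))
      readr::write_csv(summaries,
                       f <- file.path(config$out_dir, "posterior_summaries.csv"))
      emit(f)
    }

    if (stage("train")) {
      current <- "train"
      if (is.null(out$posteriors)) {
        abort("`train` requires the invert stage.", class = "gfetkin_config_error")
      }
      say("train: fitting MLP surrogate")
      tab <- build_training_table(out$expset, out$posteriors)
      readr::write_csv(tab, f <- file.path(config$out_dir, "training_table.csv"))
      emit(f)
      cfg <- config$surrogate
      fit <- train_surrogate(tab, hidden_sizes = cfg$hidden_sizes,
                             lr = cfg$lr, lr_decay = cfg$lr_decay,
                             epochs = cfg$epochs, batch = cfg$batch,
                             weight_decay = cfg$weight_decay,
                             split_seed = derive_seed(seed, "split"),
                             init_seed = derive_seed(seed, "init"))
      out$surrogate <- fit$model
      out$training_report <- fit$report
      write_surrogate(fit$model, f <- file.path(config$out_dir, "surrogate.json"))
      emit(f)
      readr::write_csv(fit$report$history,
                       f <- file.path(config$out_dir, "rmse_history.csv"))
      emit(f)
      out$training_table <- tab
    }

    if (stage("diagnostics")) {
      current <- "diagnostics"
      if (is.null(out$surrogate)) {
        abort("`diagnostics` requires the train stage.",
              class = "gfetkin_config_error")
      }
      say("diagnostics: regression report")
      out$diagnostics <- regression_diagnostics(out$surrogate,
                                                out$training_table,
                                                out$training_report$test_idx)
      pred <- predict_parameters(out$surrogate, out$training_table)
      med <- bind_rows(lapply(names(out$posteriors), function(g) {
        s <- summarize_posterior(out$posteriors[[g]])
        tibble(group_id = g,
               K_M_post = s$median[s$parameter == "K_M"],
               kcat_post = s$median[s$parameter == "k_cat"])
      }))
      out$triplets <- out$expset$truth |>
        left_join(med, by = "group_id") |>
        mutate(K_M_surrogate = pred$K_M_pred, kcat_surrogate = pred$kcat_pred)
      readr::write_csv(out$triplets,
                       f <- file.path(config$out_dir, "triplets.csv"))
      emit(f)
      readr::write_csv(out$diagnostics$stats,
                       f <- file.path(config$out_dir, "diagnostic_stats.csv"))
      emit(f)
    }
  }, error = function(e) {
    abort(sprintf("Pipeline failed in stage `%s`: %s", current,
                  conditionMessage(e)),
          class = "gfetkin_stage_error", parent = e)
  })

  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  out$manifest <- manifest
  jsonlite::write_json(
    list(master_seed = config$master_seed,
         stages = as.list(config$stages),
         files = setNames(as.list(manifest$md5), manifest$file)),
    file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  structure(out, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  ran <- names(x$config$stages)[x$config$stages]
  cat(sprintf("Pipeline run (master seed %d): stages [%s]\n",
              x$config$master_seed,
              if (length(ran)) paste(ran, collapse = ", ") else "none"))
  cat(sprintf("  %d artifact(s) in %s\n", nrow(x$manifest), x$config$out_dir))
  if (!is.null(x$training_report)) {
    cat(sprintf("  surrogate held-out R^2: log K_M %.3f, log k_cat %.3f\n",
                x$training_report$test_r2[["log_K_M"]],
                x$training_report$test_r2[["log_k_cat"]]))
  }
  invisible(x)
}
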