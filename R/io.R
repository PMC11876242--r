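#' Write / read a trajectory as tidy CSV
#'
#' Trajectories are serialised long: one row per (time, species) with
#' columns `time_s`, `species`, `value_uM`, so any downstream tool can
#' consume them without knowing the state vector.
#'
#' @param traj A `kin_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly (write); a wide tibble keyed by `time_s`
#'   (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "kin_trajectory"))
  long <- tidyr::pivot_longer(as_tibble(traj), -"time_s",
                              names_to = "species", values_to = "value_uM")
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "species", "value_uM") %in% names(long))) {
    abort("Not a tidy trajectory CSV.", class = "gfetkin_domain_error")
  }
  tidyr::pivot_wider(long, names_from = "species", values_from = "value_uM") |>
    arrange(.data$time_s)
}

#' Write / read a calibration model as JSON
#'
#' Field names carry explicit units.
#'
#' @param cal A `calibration_model`.
#' @param path Output JSON path.
#' @return `path` invisibly (write); a `calibration_model` (read).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  obj <- list(slope_uA_per_uM = cal$slope, intercept_uA = cal$intercept,
              linear_range_low_uM = unname(cal$linear_range[["low"]]),
              linear_range_high_uM = unname(cal$linear_range[["high"]]),
              r2 = cal$r2, residual_sd_uA = cal$residual_sd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- calibration_model(slope = obj$slope_uA_per_uM,
                           intercept = obj$intercept_uA,
                           linear_range = c(obj$linear_range_low_uM,
                                            obj$linear_range_high_uM),
                           residual_sd = obj$residual_sd_uA)
  out$r2 <- obj$r2
  out
}

#' Serialise a trained surrogate model to JSON
#'
#' Stores weights, input normalisation, output ranges and configuration,
#' so a model can be reloaded and produce bit-identical predictions.
#'
#' @param model A `surrogate_model`.
#' @param path Output JSON path.
#' @return `path` invisibly (write); a `surrogate_model` (read).
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "surrogate_model"))
  obj <- list(
    hidden_sizes = model$hidden_sizes,
    feature_mean = as.list(model$feature_mean),
    feature_sd = as.list(model$feature_sd),
    K_M_range = model$K_M_range, k_cat_range = model$k_cat_range,
    split_seed = model$split_seed, init_seed = model$init_seed,
    layers = lapply(model$weights, function(w) {
      list(W = as.vector(w$W), dim = dim(w$W), b = w$b)
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  weights <- lapply(obj$layers, function(l) {
    d <- as.integer(unlist(l$dim))
    list(W = matrix(num(l$W), nrow = d[1], ncol = d[2]), b = num(l$b))
  })
  K_M_range <- num(obj$K_M_range)
  k_cat_range <- num(obj$k_cat_range)
  structure(list(weights = weights,
                 feature_mean = setNames(num(obj$feature_mean),
                                         names(obj$feature_mean)),
                 feature_sd = setNames(num(obj$feature_sd),
                                       names(obj$feature_sd)),
                 lo = c(log(K_M_range[1]), log(k_cat_range[1])),
                 hi = c(log(K_M_range[2]), log(k_cat_range[2])),
                 hidden_sizes = as.integer(unlist(obj$hidden_sizes)),
                 K_M_range = K_M_range, k_cat_range = k_cat_range,
                 split_seed = num(obj$split_seed),
                 init_seed = num(obj$init_seed)),
            class = "surrogate_model")
}
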