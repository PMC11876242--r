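#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_abline autoplot
#'   labs facet_wrap geom_vline geom_ribbon theme_minimal scale_x_log10
#'   scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a kinetic trajectory
#'
#' Species concentrations against time, one facet-free line per species.
#'
#' @param object A `kin_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kin_trajectory
#' @export
autoplot.kin_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                              names_to = "species", values_to = "value_uM")
  ggplot(long, aes(x = .data$time_s, y = .data$value_uM,
                   colour = .data$species)) +
    geom_line() +
    labs(x = "time (s)", y = "concentration (uM)", colour = NULL) +
    theme_minimal()
}

#' Plot a calibration curve with its detected linear range
#'
#' @param object A `calibration_model` fitted with [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calibration_model
#' @export
autoplot.calibration_model <- function(object, ...) {
  if (is.null(object$data)) {
    abort("No calibration points stored; nothing to plot.",
          class = "gfetkin_domain_error")
  }
  ggplot(object$data, aes(x = .data$conc_uM, y = .data$delta_I_uA)) +
    geom_point(aes(colour = .data$in_linear_range)) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                linetype = 2) +
    geom_vline(xintercept = object$linear_range[["high"]], linetype = 3) +
    labs(x = "concentration (uM)", y = "|dI_ds| (uA)",
         colour = "in linear range") +
    theme_minimal()
}

#' Plot posterior marginal histograms
#'
#' @param object An `mm_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mm_posterior
#' @export
autoplot.mm_posterior <- function(object, ...) {
  long <- tidyr::pivot_longer(object$samples, c("K_M", "k_cat", "noise_sd"),
                              names_to = "parameter", values_to = "value")
  ggplot(long, aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60) +
    facet_wrap(~parameter, scales = "free") +
    scale_x_log10() +
    labs(x = NULL, y = "draws") +
    theme_minimal()
}

#' Plot the per-epoch RMSE training history
#'
#' @param object A `training_report` from [train_surrogate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot training_report
#' @export
autoplot.training_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("rmse_train", "rmse_test"),
                              names_to = "split", values_to = "rmse")
  ggplot(long, aes(x = .data$epoch, y = .data$rmse, colour = .data$split)) +
    geom_line() +
    labs(x = "epoch", y = "RMSE (log-parameter units)", colour = NULL) +
    theme_minimal()
}

#' Plot surrogate predictions against Bayesian labels
#'
#' @param object A `surrogate_diagnostics` from [regression_diagnostics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot surrogate_diagnostics
#' @export
autoplot.surrogate_diagnostics <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$label, y = .data$prediction,
                           colour = .data$split)) +
    geom_point(alpha = 0.7) +
    geom_abline(slope = 1, intercept = 0, linetype = 2) +
    facet_wrap(~parameter, scales = "free") +
    labs(x = "Bayesian inversion label", y = "surrogate prediction",
         colour = NULL) +
    theme_minimal()
}

#' Plot active-enzyme fraction across inactivation scenarios
#'
#' @param object An `inactivation_scenarios` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot inactivation_scenarios
#' @export
autoplot.inactivation_scenarios <- function(object, ...) {
  long <- bind_rows(lapply(seq_len(nrow(object)), function(i) {
    tr <- object$trajectory[[i]]
    tibble(AH2_uM = object$AH2_uM[i], time_s = tr$time_s,
           active = active_fraction(tr))
  }))
  ggplot(long, aes(x = .data$time_s, y = .data$active,
                   colour = factor(.data$AH2_uM))) +
    geom_line() +
    labs(x = "time (s)", y = "active enzyme fraction",
         colour = "cosubstrate (uM)") +
    theme_minimal()
}
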