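#' Fit a GFET calibration curve with linear-range detection
#'
#' Builds the concentration response model of a constant-voltage GFET
#' measurement from a table of known analyte concentrations and the
#' absolute drain-current changes they produce. Amperometric calibration
#' curves are linear at low concentration and saturate; the linear range is
#' detected by growing a window from the lowest concentration upward: the
#' largest contiguous prefix of the (sorted) concentrations whose
#' ordinary-least-squares fit reaches `r2_min` is reported, and the slope
#' and intercept come from that window.
#'
#' @param data Data frame with one row per calibration point.
#' @param conc,delta_I Column names (strings) holding concentration (uM)
#'   and absolute current change (uA). Defaults `"conc_uM"`, `"delta_I_uA"`.
#' @param r2_min Minimum r-squared a window must attain to count as linear
#'   (default 0.99).
#' @return An object of class `calibration_model` with fields `slope`
#'   (uA/uM), `intercept` (uA), `linear_range` (low/high, uM), `r2`,
#'   `residual_sd` (uA), `n_points`, and the calibration `data` used.
#' @export
#' @examples
#' cal_tbl <- tibble::tibble(conc_uM = seq(10, 70, 10),
#'                           delta_I_uA = 2 * seq(10, 70, 10))
#' fit_calibration(cal_tbl)
fit_calibration <- function(data, conc = "conc_uM", delta_I = "delta_I_uA",
                            r2_min = 0.99) {
  df <- as.data.frame(data)
  if (!all(c(conc, delta_I) %in% names(df))) {
    abort("Calibration table lacks the requested columns.",
          class = "gfetkin_domain_error")
  }
  x <- df[[conc]]
  y <- df[[delta_I]]
  if (length(x) < 4L) {
    abort("Need at least 4 calibration points.", class = "gfetkin_domain_error")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Calibration points must be finite.", class = "gfetkin_domain_error")
  }
  if (anyDuplicated(x)) {
    abort("Concentrations must be distinct.", class = "gfetkin_domain_error")
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  check_scalar(r2_min, "r2_min", positive = TRUE)

  window_fit <- function(k) {
    xi <- x[1:k]; yi <- y[1:k]
    sst <- sum((yi - mean(yi))^2)
    if (sst == 0) return(NULL) # degenerate: constant response
    fit <- lm(yi ~ xi)
    r2 <- 1 - sum(fit$residuals^2) / sst
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r2 = r2, residual_sd = sqrt(sum(fit$residuals^2) / max(1, k - 2)),
         k = k)
  }

  best <- NULL
  for (k in seq(length(x), 3L)) { # largest window first
    w <- window_fit(k)
    if (!is.null(w) && w$r2 >= r2_min && w$slope != 0) {
      best <- w
      break
    }
  }
  if (is.null(best)) {
    abort("No contiguous low-concentration window of >= 3 points reaches the requested r-squared; calibration failed.",
          class = "gfetkin_calibration_failure")
  }
  structure(list(slope = best$slope, intercept = best$intercept,
                 linear_range = c(low = x[1], high = x[best$k]),
                 r2 = best$r2, residual_sd = best$residual_sd,
                 n_points = best$k,
                 data = tibble(conc_uM = x, delta_I_uA = y,
                               in_linear_range = seq_along(x) <= best$k)),
            class = "calibration_model")
}

#' Construct a calibration model directly from known coefficients
#'
#' Used when the transducer response is specified rather than fitted, e.g.
#' as the ground-truth sensor model of a synthetic study.
#'
#' @param slope Response slope, uA/uM (nonzero).
#' @param intercept Response intercept, uA.
#' @param linear_range Length-2 numeric, low/high bounds of the linear
#'   range in uM.
#' @param residual_sd Residual standard deviation, uA.
#' @return A `calibration_model`.
#' @export
calibration_model <- function(slope, intercept = 0,
                              linear_range = c(10, 70), residual_sd = 0) {
  check_scalar(slope, "slope")
  if (slope == 0) abort("`slope` must be nonzero.", class = "gfetkin_domain_error")
  check_scalar(intercept, "intercept")
  stopifnot(is.numeric(linear_range), length(linear_range) == 2L,
            linear_range[1] < linear_range[2])
  structure(list(slope = slope, intercept = intercept,
                 linear_range = c(low = linear_range[1], high = linear_range[2]),
                 r2 = 1, residual_sd = residual_sd, n_points = NA_integer_,
                 data = NULL),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("GFET calibration model (|dI_ds| vs concentration)\n")
  cat(sprintf("  slope = %.4g uA/uM, intercept = %.4g uA\n", x$slope, x$intercept))
  cat(sprintf("  linear range: %g - %g uM (r2 = %.4f, residual sd = %.3g uA)\n",
              x$linear_range[["low"]], x$linear_range[["high"]], x$r2,
              x$residual_sd))
  invisible(x)
}

# Smooth plateau: identity up to `high`, then a rational saturation that
# approaches high + width with unit slope at the junction (C1 continuous).
# The default width makes the declared linear-range endpoint a real
# breakpoint: the response departs visibly from the line just above it.
saturate_conc <- function(conc, high, width = 0.15 * high) {
  over <- conc > high
  out <- conc
  ex <- conc[over] - high
  out[over] <- high + width * ex / (ex + width)
  out
}

#' Synthesize a constant-voltage GFET current trace from product kinetics
#'
#' Forward sensor model: the drain-source current at constant gate and
#' drain voltage follows the oxidised-product concentration through the
#' calibration line, with a smooth plateau above the linear range and
#' additive Gaussian measurement noise:
#' `I(t) = baseline + slope * sat(P(t)) + intercept + N(0, noise_sd)`.
#'
#' @param product Data frame with columns `time_s` and a product
#'   concentration column `conc_uM` (uM), or a `kin_trajectory` (its `P`
#'   column is used).
#' @param cal A `calibration_model`.
#' @param noise_sd Gaussian noise standard deviation, uA.
#' @param seed Mandatory integer seed; identical seeds give identical
#'   traces.
#' @param baseline_uA Baseline current at zero product, uA.
#' @param V_g_mV,V_ds_mV Constant gate / drain voltages recorded with the
#'   trace, mV.
#' @param condition_id Identifier linking the trace to an experimental
#'   condition.
#' @return A tibble of class `current_trace` with columns
#'   `time_s, I_ds_uA, V_g_mV, V_ds_mV, condition_id`.
#' @export
concentration_to_current <- function(product, cal, noise_sd = 0, seed,
                                     baseline_uA = 10, V_g_mV = 500,
                                     V_ds_mV = 500, condition_id = "trace") {
  stopifnot(inherits(cal, "calibration_model"))
  if (missing(seed)) abort("`seed` is mandatory.", class = "gfetkin_domain_error")
  check_scalar(noise_sd, "noise_sd", non_negative = TRUE)
  df <- as.data.frame(product)
  pcol <- if ("conc_uM" %in% names(df)) "conc_uM" else "P"
  if (!all(c("time_s", pcol) %in% names(df))) {
    abort("`product` must carry `time_s` and a product concentration column.",
          class = "gfetkin_domain_error")
  }
  p <- df[[pcol]]
  if (any(p < 0)) abort("Product must be non-negative.", class = "gfetkin_domain_error")
  sat <- saturate_conc(p, cal$linear_range[["high"]])
  noise <- with_seed(seed, rnorm(length(p), 0, noise_sd))
  out <- tibble(time_s = df$time_s,
                I_ds_uA = baseline_uA + cal$slope * sat + cal$intercept + noise,
                V_g_mV = V_g_mV, V_ds_mV = V_ds_mV,
                condition_id = condition_id)
  class(out) <- c("current_trace", class(out))
  out
}

#' Map a constant-voltage current trace back to product concentration
#'
#' Inverse sensor model. The per-trace baseline is the current at the
#' first sample (the current returns to baseline after washing, so each
#' trace carries its own reference), and
#' `c(t) = (|I(t) - I(0)| - intercept) / slope`, clamped at zero.
#' Values outside the calibration's linear range are flagged
#' (`in_range = FALSE`) but never dropped.
#'
#' @param trace A `current_trace` (or data frame with `time_s`, `I_ds_uA`).
#' @param cal A `calibration_model`.
#' @return Tibble with columns `time_s`, `conc_uM`, `in_range`.
#' @export
current_to_concentration <- function(trace, cal) {
  stopifnot(inherits(cal, "calibration_model"))
  if (cal$slope == 0) abort("Calibration slope is zero.", class = "gfetkin_domain_error")
  df <- as.data.frame(trace)
  if (!all(c("time_s", "I_ds_uA") %in% names(df))) {
    abort("`trace` must carry `time_s` and `I_ds_uA`.",
          class = "gfetkin_domain_error")
  }
  dI <- abs(df$I_ds_uA - df$I_ds_uA[1])
  conc <- pmax((dI - cal$intercept) / cal$slope, 0)
  tibble(time_s = df$time_s, conc_uM = conc,
         in_range = conc >= cal$linear_range[["low"]] &
           conc <= cal$linear_range[["high"]])
}
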