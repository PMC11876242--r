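#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows group_by summarise ungroup left_join
#' @importFrom stats rnorm runif quantile median sd lm coef setNames var
NULL

# Internal: check a scalar is a finite number, optionally positive/non-negative
check_scalar <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "gfetkin_domain_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name),
          class = "gfetkin_domain_error")
  }
  if (non_negative && x < 0) {
    abort(sprintf("`%s` must be non-negative.", name),
          class = "gfetkin_domain_error")
  }
  invisible(x)
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || anyNA(times) ||
      any(!is.finite(times)) || any(diff(times) <= 0)) {
    abort("`times` must be a strictly increasing numeric grid.",
          class = "gfetkin_domain_error")
  }
  invisible(times)
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Counter/label-based seed derivation so every stochastic stage of a study
#' gets its own stream, reproducibly and independently of execution order.
#' The derived seed is a deterministic 31-bit hash of `(master_seed, label)`.
#'
#' @param master_seed Single integer master seed.
#' @param label Character scalar naming the consumer (e.g. a condition id).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "condition_001")
derive_seed <- function(master_seed, label) {
  check_scalar(master_seed, "master_seed")
  stopifnot(is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  h <- as.numeric(master_seed) %% m
  bytes <- utf8ToInt(label)
  for (b in bytes) {
    h <- (h * 31 + b) %% m
  }
  # final mix to decorrelate nearby labels
  h <- (h * 48271) %% m
  as.integer(h + 1)
}

# Evaluate an expression under a local RNG state restored on exit
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
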