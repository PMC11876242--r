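#' Assemble the surrogate training table from inversion results
#'
#' Joins the condition features of a synthetic study with
#' Bayesian-inversion labels: the posterior medians of the Michaelis
#' constant and turnover number, log-transformed. Alignment is by id, not
#' list order. Because a single substrate series yields one posterior, the
#' posterior list may be keyed either by `condition_id` or by `group_id`
#' (every condition in the group then shares the label).
#'
#' @param expset An `experiment_set`.
#' @param posteriors Named list of `mm_posterior` objects keyed by
#'   condition id or group id.
#' @return Tibble with one row per condition: `condition_id`, one-hot
#'   enzyme and substrate indicators, `pH`, `temperature_C`,
#'   `substrate_conc_uM`, and labels `log_K_M`, `log_k_cat`.
#' @export
build_training_table <- function(expset, posteriors) {
  stopifnot(inherits(expset, "experiment_set"), is.list(posteriors))
  if (is.null(names(posteriors)) || any(names(posteriors) == "")) {
    abort("`posteriors` must be a fully named list.", class = "gfetkin_domain_error")
  }
  conds <- expset$conditions
  key <- ifelse(conds$condition_id %in% names(posteriors),
                conds$condition_id, conds$group_id)
  missing_ids <- conds$condition_id[!key %in% names(posteriors)]
  if (length(missing_ids)) {
    abort(paste0("Missing posterior for condition(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "gfetkin_domain_error")
  }
  labels <- purrr::map(key, function(k) {
    s <- summarize_posterior(posteriors[[k]])
    c(log_K_M = log(s$median[s$parameter == "K_M"]),
      log_k_cat = log(s$median[s$parameter == "k_cat"]))
  })
  lab <- do.call(rbind, labels)
  tibble(condition_id = conds$condition_id,
         enzyme_HRP = as.numeric(conds$enzyme == "HRP"),
         enzyme_heme = as.numeric(conds$enzyme == "heme"),
         substrate_ABTS = as.numeric(conds$substrate == "ABTS"),
         substrate_H2O2 = as.numeric(conds$substrate == "H2O2"),
         pH = conds$pH, temperature_C = conds$temperature_C,
         substrate_conc_uM = conds$substrate_conc_uM,
         log_K_M = lab[, "log_K_M"], log_k_cat = lab[, "log_k_cat"])
}

feature_cols <- c("enzyme_HRP", "enzyme_heme", "substrate_ABTS",
                  "substrate_H2O2", "pH", "temperature_C", "substrate_conc_uM")
label_cols <- c("log_K_M", "log_k_cat")

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_forward <- function(weights, X) {
  a <- X
  zs <- list(); as_ <- list(a)
  L <- length(weights)
  for (l in seq_len(L)) {
    z <- sweep(a %*% weights[[l]]$W, 2, weights[[l]]$b, "+")
    zs[[l]] <- z
    a <- if (l < L) relu(z) else sigmoid(z)
    as_[[l + 1]] <- a
  }
  list(out = a, zs = zs, as_ = as_)
}

#' Train the MLP surrogate for kinetic-parameter prediction
#'
#' A fully connected multilayer perceptron mapping condition features
#' (enzyme and substrate indicators, pH, temperature, substrate
#' concentration) to log kinetic parameters. Hidden layers use the
#' rectifier; the output layer is logistic, mapped affinely onto the
#' declared per-parameter log-ranges, so predictions can never leave those
#' ranges. Trained by the Adam optimiser on the mean-squared error of the
#' range-normalised log-parameters, with an 80/20 train/test split
#' stratified by enzyme and the per-epoch train and test RMSE recorded.
#'
#' @param table Training table from [build_training_table()] (>= 20 rows).
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param lr Adam learning rate.
#' @param lr_decay Multiplicative per-epoch learning-rate decay.
#' @param epochs Training epochs.
#' @param batch Minibatch size (default 32); `NULL` trains full-batch.
#' @param weight_decay L2 penalty on the weight matrices (not biases),
#'   the regularisation keeping the fitted surface smooth between
#'   training conditions.
#' @param split_seed,init_seed Seeds fixing the train/test split and the
#'   weight initialisation.
#' @param test_fraction Held-out fraction (default 0.2).
#' @param K_M_range,k_cat_range Output ranges in natural units; the
#'   logistic output is mapped onto their logs.
#' @return List with `model` (a `surrogate_model`) and `report` (a
#'   `training_report`: `history` tibble of per-epoch train/test RMSE in
#'   log-parameter units, final per-parameter test RMSE and R-squared,
#'   split indices and optimiser settings).
#' @export
train_surrogate <- function(table, hidden_sizes = 16, lr = 0.01,
                            lr_decay = 0.99, epochs = 800, batch = 32,
                            weight_decay = 1e-4,
                            split_seed = 1, init_seed = 2,
                            test_fraction = 0.2,
                            K_M_range = c(1, 1e4), k_cat_range = c(1e-2, 1e3)) {
  df <- as.data.frame(table)
  if (nrow(df) < 20L) {
    abort("Need at least 20 training rows.", class = "gfetkin_domain_error")
  }
  stopifnot(all(c(feature_cols, label_cols) %in% names(df)),
            all(hidden_sizes > 0), epochs >= 1, lr > 0)
  lo <- c(log(K_M_range[1]), log(k_cat_range[1]))
  hi <- c(log(K_M_range[2]), log(k_cat_range[2]))
  Y <- as.matrix(df[, label_cols])
  if (any(Y < matrix(lo, nrow(Y), 2, byrow = TRUE)) ||
      any(Y > matrix(hi, nrow(Y), 2, byrow = TRUE))) {
    abort("Labels fall outside the declared parameter ranges.",
          class = "gfetkin_domain_error")
  }

  # 80/20 split stratified by enzyme
  test_idx <- with_seed(split_seed, {
    idx <- integer(0)
    for (g in unique(df$enzyme_HRP)) {
      rows <- which(df$enzyme_HRP == g)
      n_test <- max(1L, round(test_fraction * length(rows)))
      idx <- c(idx, sample(rows, n_test))
    }
    sort(idx)
  })
  train_idx <- setdiff(seq_len(nrow(df)), test_idx)

  X_all <- as.matrix(df[, feature_cols])
  mu <- colMeans(X_all[train_idx, , drop = FALSE])
  sg <- apply(X_all[train_idx, , drop = FALSE], 2, sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  Xn <- sweep(sweep(X_all, 2, mu), 2, sg, "/")
  # labels normalised onto [0,1] within the declared log-ranges
  Y01 <- sweep(sweep(Y, 2, lo), 2, hi - lo, "/")

  sizes <- c(length(feature_cols), hidden_sizes, 2L)
  weights <- with_seed(init_seed, {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]
      list(W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                      fan_in, sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
  mstate <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))
  vstate <- lapply(weights, function(w) list(W = w$W * 0, b = w$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  rmse_log <- function(idx) {
    pred01 <- mlp_forward(weights, Xn[idx, , drop = FALSE])$out
    pred <- sweep(sweep(pred01, 2, hi - lo, "*"), 2, lo, "+")
    sqrt(mean((pred - Y[idx, , drop = FALSE])^2))
  }

  n_train <- length(train_idx)
  batch_size <- if (is.null(batch)) n_train else min(batch, n_train)
  history <- matrix(NA_real_, epochs, 2,
                    dimnames = list(NULL, c("train", "test")))
  cur_lr <- lr
  order_seed <- derive_seed(split_seed, "epoch_order")

  for (ep in seq_len(epochs)) {
    ord <- if (batch_size < n_train) {
      with_seed(order_seed + ep, sample(train_idx))
    } else train_idx
    for (start in seq(1, n_train, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n_train)]
      Xb <- Xn[idx, , drop = FALSE]
      Yb <- Y01[idx, , drop = FALSE]
      fw <- mlp_forward(weights, Xb)
      yhat <- fw$out
      if (any(!is.finite(yhat))) {
        abort(sprintf("Training produced non-finite loss at epoch %d.", ep),
              class = "gfetkin_training_failure")
      }
      nK <- length(Yb)
      delta <- (2 / nK) * (yhat - Yb) * yhat * (1 - yhat) # sigmoid output
      grads <- vector("list", length(weights))
      for (l in rev(seq_along(weights))) {
        a_prev <- fw$as_[[l]]
        grads[[l]] <- list(W = crossprod(a_prev, delta) +
                             weight_decay * weights[[l]]$W,
                           b = colSums(delta))
        if (l > 1) {
          delta <- (delta %*% t(weights[[l]]$W)) * (fw$zs[[l - 1]] > 0)
        }
      }
      t_step <- t_step + 1L
      for (l in seq_along(weights)) {
        for (part in c("W", "b")) {
          g <- grads[[l]][[part]]
          mstate[[l]][[part]] <- beta1 * mstate[[l]][[part]] + (1 - beta1) * g
          vstate[[l]][[part]] <- beta2 * vstate[[l]][[part]] + (1 - beta2) * g^2
          mhat <- mstate[[l]][[part]] / (1 - beta1^t_step)
          vhat <- vstate[[l]][[part]] / (1 - beta2^t_step)
          weights[[l]][[part]] <- weights[[l]][[part]] -
            cur_lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    history[ep, "train"] <- rmse_log(train_idx)
    history[ep, "test"] <- rmse_log(test_idx)
    cur_lr <- cur_lr * lr_decay
  }

  model <- structure(list(weights = weights, feature_mean = mu,
                          feature_sd = sg, lo = lo, hi = hi,
                          hidden_sizes = hidden_sizes,
                          K_M_range = K_M_range, k_cat_range = k_cat_range,
                          split_seed = split_seed, init_seed = init_seed),
                     class = "surrogate_model")
  test_pred <- predict_parameters(model, df[test_idx, , drop = FALSE])
  r2 <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((obs - pred)^2) / sst
  }
  report <- structure(list(
    history = tibble(epoch = seq_len(epochs),
                     rmse_train = history[, "train"],
                     rmse_test = history[, "test"]),
    final_test_rmse = c(log_K_M = sqrt(mean((log(test_pred$K_M_pred) -
                                               Y[test_idx, 1])^2)),
                        log_k_cat = sqrt(mean((log(test_pred$kcat_pred) -
                                                 Y[test_idx, 2])^2))),
    test_r2 = c(log_K_M = r2(Y[test_idx, 1], log(test_pred$K_M_pred)),
                log_k_cat = r2(Y[test_idx, 2], log(test_pred$kcat_pred))),
    train_idx = train_idx, test_idx = test_idx,
    optimizer = list(name = "adam", lr = lr, lr_decay = lr_decay,
                     beta1 = beta1, beta2 = beta2, epochs = epochs,
                     batch = batch_size, weight_decay = weight_decay)),
    class = "training_report")
  list(model = model, report = report)
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("MLP surrogate: %d features -> [%s] -> 2 log-parameters\n",
              length(x$feature_mean), paste(x$hidden_sizes, collapse = ", ")))
  cat(sprintf("  output ranges: K_M in [%g, %g] uM, k_cat in [%g, %g] 1/s\n",
              x$K_M_range[1], x$K_M_range[2], x$k_cat_range[1], x$k_cat_range[2]))
  invisible(x)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("Surrogate training report: %d epochs (%s, lr %g)\n",
              nrow(x$history), x$optimizer$name, x$optimizer$lr))
  cat(sprintf("  final test RMSE (log units): K_M %.4f, k_cat %.4f\n",
              x$final_test_rmse[["log_K_M"]], x$final_test_rmse[["log_k_cat"]]))
  cat(sprintf("  held-out R^2: log K_M %.3f, log k_cat %.3f\n",
              x$test_r2[["log_K_M"]], x$test_r2[["log_k_cat"]]))
  invisible(x)
}

#' Predict kinetic parameters for new conditions
#'
#' Deterministic forward pass of a trained surrogate. Outputs are
#' guaranteed to lie inside the model's declared parameter ranges because
#' the logistic output is mapped onto their logs. A warning is raised when
#' a feature lies far outside the normalisation support seen in training
#' (beyond 4 training standard deviations).
#'
#' @param model A `surrogate_model`.
#' @param newdata Data frame carrying the feature columns (as produced by
#'   [build_training_table()]).
#' @return Tibble with `K_M_pred` (uM) and `kcat_pred` (1/s) per row.
#' @export
predict_parameters <- function(model, newdata) {
  stopifnot(inherits(model, "surrogate_model"))
  df <- as.data.frame(newdata)
  if (!all(feature_cols %in% names(df))) {
    abort("`newdata` lacks required feature columns.",
          class = "gfetkin_domain_error")
  }
  X <- as.matrix(df[, feature_cols])
  if (anyNA(X) || any(!is.finite(X))) {
    abort("Features must be finite.", class = "gfetkin_domain_error")
  }
  onehot_ok <- (df$enzyme_HRP + df$enzyme_heme == 1) &
    (df$substrate_ABTS + df$substrate_H2O2 == 1)
  if (!all(onehot_ok)) {
    abort("Exactly one enzyme and one substrate indicator must be active.",
          class = "gfetkin_domain_error")
  }
  Xn <- sweep(sweep(X, 2, model$feature_mean), 2, model$feature_sd, "/")
  if (any(abs(Xn) > 4)) {
    warn("Some features lie outside the normalisation support seen in training.")
  }
  out01 <- mlp_forward(model$weights, Xn)$out
  logp <- sweep(sweep(out01, 2, model$hi - model$lo, "*"), 2, model$lo, "+")
  tibble(K_M_pred = exp(logp[, 1]), kcat_pred = exp(logp[, 2]))
}

#' Regression diagnostics of surrogate versus Bayesian labels
#'
#' Per-parameter comparison of surrogate predictions against the
#' Bayesian-inversion labels they were trained on, with train/test
#' membership flags, the standard goodness-of-fit statistics, and the
#' scatter pairs behind them.
#'
#' @param model A `surrogate_model`.
#' @param table Training table from [build_training_table()].
#' @param test_idx Optional integer vector of held-out rows to flag.
#' @return List with `pairs` (tibble `condition_id, parameter, label,
#'   prediction, split`) and `stats` (tibble `parameter, split, r2, rmse`),
#'   class `surrogate_diagnostics`.
#' @export
regression_diagnostics <- function(model, table, test_idx = integer(0)) {
  df <- as.data.frame(table)
  pred <- predict_parameters(model, df)
  split <- ifelse(seq_len(nrow(df)) %in% test_idx, "test", "train")
  pairs <- bind_rows(
    tibble(condition_id = df$condition_id, parameter = "log_K_M",
           label = df$log_K_M, prediction = log(pred$K_M_pred), split = split),
    tibble(condition_id = df$condition_id, parameter = "log_k_cat",
           label = df$log_k_cat, prediction = log(pred$kcat_pred),
           split = split))
  stats_tbl <- pairs |>
    group_by(.data$parameter, .data$split) |>
    summarise(r2 = {
      sst <- sum((.data$label - mean(.data$label))^2)
      if (sst == 0) NA_real_ else 1 - sum((.data$label - .data$prediction)^2) / sst
    },
    rmse = sqrt(mean((.data$label - .data$prediction)^2)),
    .groups = "drop")
  structure(list(pairs = pairs, stats = stats_tbl),
            class = "surrogate_diagnostics")
}
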