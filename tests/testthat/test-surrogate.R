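test_that("the training table aligns features and inversion labels by id", {
  es <- small_expset()
  groups <- unique(es$conditions$group_id)
  posts <- setNames(lapply(seq_along(groups),
                           function(i) fake_posterior(100 + i, 10 + i)),
                    groups)
  tab <- build_training_table(es, posts)
  expect_equal(nrow(tab), nrow(es$conditions))
  expect_true(all(tab$enzyme_HRP + tab$enzyme_heme == 1))
  expect_true(all(tab$substrate_ABTS + tab$substrate_H2O2 == 1))

  # degenerate posterior -> label equals its value, log-transformed
  g1 <- es$conditions$group_id[1]
  i1 <- which(groups == g1)
  expect_equal(tab$log_K_M[1], log(100 + i1))
  expect_equal(tab$log_k_cat[1], log(10 + i1))

  # order invariance: shuffled posterior list gives the identical table
  tab2 <- build_training_table(es, posts[rev(names(posts))])
  expect_identical(tab, tab2)

  # missing posterior errors and names the orphaned conditions
  expect_error(build_training_table(es, posts[-1]),
               regexp = groups[1], class = "gfetkin_domain_error")
})

test_that("constant labels are fitted to near-zero RMSE", {
  tab <- linear_law_table(n = 60)
  tab$log_K_M <- log(150)
  tab$log_k_cat <- log(20)
  # strong smoothing: the target carries no feature signal at all
  fit <- train_surrogate(tab, hidden_sizes = 16, epochs = 800,
                         weight_decay = 1e-3, split_seed = 1, init_seed = 2)
  expect_lt(utils::tail(fit$report$history$rmse_test, 1), 0.05)
  pred <- predict_parameters(fit$model, tab)
  expect_equal(unname(pred$K_M_pred), rep(150, 60), tolerance = 0.1)
  expect_equal(unname(pred$kcat_pred), rep(20, 60), tolerance = 0.1)
})

test_that("a smooth log-linear parameter law is recovered on held-out data", {
  tab <- linear_law_table(n = 200)
  fit <- train_surrogate(tab, split_seed = 5, init_seed = 6)
  expect_gte(fit$report$test_r2[["log_K_M"]], 0.95)
  expect_gte(fit$report$test_r2[["log_k_cat"]], 0.95)
  # split is a partition
  expect_setequal(c(fit$report$train_idx, fit$report$test_idx), seq_len(200))
  expect_length(intersect(fit$report$train_idx, fit$report$test_idx), 0)
  expect_equal(length(fit$report$test_idx), 40)
})

test_that("training is deterministic under its seeds", {
  tab <- linear_law_table(n = 60)
  a <- train_surrogate(tab, hidden_sizes = c(8), epochs = 50,
                       split_seed = 3, init_seed = 4)
  b <- train_surrogate(tab, hidden_sizes = c(8), epochs = 50,
                       split_seed = 3, init_seed = 4)
  expect_identical(a$report$history, b$report$history)
  expect_identical(a$model$weights, b$model$weights)
  c <- train_surrogate(tab, hidden_sizes = c(8), epochs = 50,
                       split_seed = 3, init_seed = 5)
  expect_false(identical(a$model$weights, c$model$weights))
})

test_that("predictions never leave the declared parameter ranges", {
  tab <- linear_law_table(n = 40)
  fit <- train_surrogate(tab, hidden_sizes = c(8), epochs = 30,
                         split_seed = 1, init_seed = 1)
  # adversarial far-out-of-support inputs
  wild <- tab
  wild$pH <- seq(-50, 50, length.out = 40)
  wild$temperature_C <- seq(-500, 500, length.out = 40)
  wild$substrate_conc_uM <- 10^seq(-3, 8, length.out = 40)
  pred <- suppressWarnings(predict_parameters(fit$model, wild))
  expect_true(all(pred$K_M_pred >= 1 & pred$K_M_pred <= 1e4))
  expect_true(all(pred$kcat_pred >= 1e-2 & pred$kcat_pred <= 1e3))
  expect_warning(predict_parameters(fit$model, wild), "support")

  # identical conditions give identical outputs
  two <- tab[c(1, 1), ]
  p2 <- predict_parameters(fit$model, two)
  expect_identical(p2[1, ], p2[2, ])

  # malformed one-hot rejected
  bad <- tab
  bad$enzyme_HRP[1] <- 1
  bad$enzyme_heme[1] <- 1
  expect_error(predict_parameters(fit$model, bad), class = "gfetkin_domain_error")
  expect_error(predict_parameters(fit$model, tab[, -2]),
               class = "gfetkin_domain_error")
})

test_that("regression diagnostics match the independent R-squared formula", {
  tab <- linear_law_table(n = 50)
  fit <- train_surrogate(tab, hidden_sizes = c(16), epochs = 200,
                         split_seed = 2, init_seed = 3)
  diag <- regression_diagnostics(fit$model, tab, fit$report$test_idx)
  for (par in c("log_K_M", "log_k_cat")) {
    for (sp in c("train", "test")) {
      pr <- dplyr::filter(diag$pairs, parameter == par, split == sp)
      st <- dplyr::filter(diag$stats, parameter == par, split == sp)
      expect_equal(st$r2, r2_oracle(pr$label, pr$prediction), tolerance = 1e-12)
      expect_equal(st$rmse, sqrt(mean((pr$label - pr$prediction)^2)),
                   tolerance = 1e-12)
    }
  }
  # a perfect predictor scores R^2 = 1, RMSE = 0; the label mean scores 0
  lab <- dplyr::filter(diag$pairs, parameter == "log_K_M", split == "train")$label
  expect_equal(r2_oracle(lab, lab), 1)
  expect_equal(r2_oracle(lab, rep(mean(lab), length(lab))), 0)
})

test_that("labels outside the declared output ranges are rejected", {
  tab <- linear_law_table(n = 30)
  tab$log_K_M[5] <- log(1e6)
  expect_error(train_surrogate(tab, epochs = 5), class = "gfetkin_domain_error")
  expect_error(train_surrogate(linear_law_table(n = 10), epochs = 5),
               class = "gfetkin_domain_error") # too few rows
})

test_that("surrogate models round-trip through JSON with identical predictions", {
  tab <- linear_law_table(n = 40)
  fit <- train_surrogate(tab, hidden_sizes = c(8, 8), epochs = 50,
                         split_seed = 1, init_seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(fit$model, path)
  back <- read_surrogate(path)
  expect_equal(predict_parameters(back, tab), predict_parameters(fit$model, tab),
               tolerance = 1e-12)
})
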