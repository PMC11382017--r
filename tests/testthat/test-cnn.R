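test_that("pearson matches the product-moment definition", {
  a <- c(1, 5, 3, 8, 2)
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, -a), -1)
  # frozen from direct evaluation of the product-moment formula (equals
  # stats::cor): 2 / sqrt(2 * 14/3)
  expect_equal(pearson(c(1, 2, 3), c(2, 1, 4)), 0.654653670707977,
               tolerance = 1e-12)
  expect_equal(pearson(c(1, 2, 3), c(2, 1, 4)), cor(c(1, 2, 3), c(2, 1, 4)))
  # affine invariance
  b <- c(2, 1, 4, 9, 0)
  expect_equal(pearson(a, 2 * b + 5), pearson(a, b))
  # degeneracy signaled as NA, not an error
  expect_true(is.na(pearson(c(1, 1, 1), 1:3)))
  expect_true(is.na(pearson(1:2, 2:3)))
})

test_that("compiled convolution matches a direct loop oracle", {
  set.seed(8)
  x <- array(rnorm(10 * 7 * 2), c(10, 7, 2))
  W <- matrix(rnorm(3 * 18), 3, 18)
  b <- rnorm(3)
  got <- lspheno:::conv3x3_forward_cpp(x, W, b)
  expect_equal(got, conv3_oracle(x, W, b), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("model building enforces shape contracts", {
  spec <- model_spec("rgb_dsm", conv_filters = c(4, 8), fc_dims = c(16),
                     dropout_rate = 0)
  expect_error(build_model(spec, 34, 32), "block 2")

  model <- build_model(spec, 32, 32, seed = 1)
  x <- array(rnorm(32 * 32 * 4 * 2), c(32, 32, 4, 2))
  out <- cnn_forward(model, x)
  expect_identical(dim(out$features), c(2L, 30L))
  expect_identical(dim(out$preds), c(2L, 5L))

  # channel guard
  x3 <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  expect_error(cnn_forward(model, x3), "4 input channels")

  # zero-weight head: every estimate equals the bias
  model$params$head_W[] <- 0
  model$params$head_b <- c(1, 2, 3, 4, 5)
  out0 <- cnn_forward(model, x)
  expect_equal(out0$preds, matrix(1:5, 2, 5, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("the linear head is exact: estimates = X W + 1 b'", {
  tr <- small_trained()
  x <- build_input(tr$ds, tr$spec)
  feats <- extract_features(tr$fit$model, x)
  recon <- sweep(feats$X %*% feats$W, 2, feats$b, `+`)
  expect_lt(max(abs(recon - feats$preds)), 1e-6)
  # scaling contract on the reference set
  expect_lt(max(abs(colMeans(feats$X))), 1e-8)
  # matrix form equals the per-trait dot-product form for random inputs
  k <- 3
  est_k <- as.numeric(feats$X[k, ] %*% feats$W + feats$b)
  expect_equal(est_k, unname(feats$preds[k, ]), tolerance = 1e-10)
})

test_that("feature extraction on augmented copies keeps row count", {
  tr <- small_trained()
  x <- build_input(tr$ds, tr$spec, 1:10)
  a <- lspheno:::augment_tensor(x, matrix(0, 10, 5))
  feats <- extract_features(tr$fit$model, a$x)
  expect_identical(nrow(feats$X), 40L)
})

test_that("training is deterministic and checkpoint selection is sound", {
  ds <- small_dataset()
  spec <- model_spec("dsm", conv_filters = c(4, 8), fc_dims = c(16),
                     dropout_rate = 0.1)
  x <- build_input(ds, spec, 1:24)
  y <- ds$traits$normalized[1:24, ]
  xv <- build_input(ds, spec, 25:36)
  yv <- ds$traits$normalized[25:36, ]
  cfg <- train_config(epochs = 3, batch_size = 8, seed = 77)
  f1 <- train_model(build_model(spec, 32, 32, seed = 5), x, y, xv, yv, cfg)
  f2 <- train_model(build_model(spec, 32, 32, seed = 5), x, y, xv, yv, cfg)
  expect_identical(f1$log$val_mse, f2$log$val_mse)
  # returned checkpoint's validation MSE <= final epoch's
  expect_lte(f1$best_val_mse, f1$log$val_mse[nrow(f1$log)])
})

test_that("constant-zero targets drive the MSE toward the floor", {
  ds <- small_dataset()
  spec <- model_spec("dsm", conv_filters = c(4), fc_dims = c(8),
                     dropout_rate = 0)
  x <- build_input(ds, spec, 1:20)
  y0 <- matrix(0, 20, 5)
  fit <- train_model(build_model(spec, 32, 32, seed = 1), x, y0, x, y0,
                     train_config(epochs = 15, batch_size = 20, seed = 1))
  expect_lt(fit$best_val_mse, 0.05)
})

test_that("cross-validation folds partition units and metrics are complete", {
  scheme <- cv_scheme(k = 4, repetitions = 2, unit = "accession", seed = 3)
  units <- sprintf("ACC%03d", 1:12)
  f1 <- fold_map(scheme, 1, units)
  expect_setequal(names(f1), units)
  expect_true(all(table(f1) == 3))
  expect_identical(f1, fold_map(scheme, 1, units)) # deterministic
  expect_false(identical(f1, fold_map(scheme, 2, units)))
})

test_that("crossvalidate reports per-treatment metrics and flags small folds", {
  ds <- small_dataset()
  spec <- model_spec("dsm", conv_filters = c(4), fc_dims = c(8),
                     dropout_rate = 0)
  cv <- crossvalidate(ds, spec, train_config(epochs = 1, batch_size = 16),
                      cv_scheme(k = 3, repetitions = 1, unit = "accession"))
  expect_setequal(unique(cv$metrics$subgroup),
                  c("overall", "control", "drought"))
  # every fold emits one row per trait and subgroup
  expect_equal(nrow(cv$metrics), 3 * 3 * 5)
  expect_true(all(c("trait", "subgroup", "mean_r", "sd_r") %in%
                    colnames(cv$summary)))
})
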