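test_that("min-max rescaling matches the published normalization ranges", {
  spec <- default_normalization()
  expect_equal(unname(rescale(cbind(cellulose = 50), spec)[1]), 1)
  expect_equal(unname(rescale(cbind(urea = 0), spec)[1]), 0)
  expect_equal(unname(rescale(cbind(SA2BSS = 25), spec)[1]), 0.5)  # (25-10)/30
  x <- cbind(cellulose = c(0, 12.5, 50), PA2DSS = c(10, 31, 40))
  expect_equal(rescale(rescale(x, spec, "to_unit"), spec, "to_original"), x,
               tolerance = 1e-12)
  expect_error(rescale(cbind(urea = 11), spec), "urea")
  expect_error(rescale(cbind(nonsense = 1), spec), "nonsense")
})

test_that("the autoencoder reconstructs a rank-4 affine manifold", {
  A <- affine_manifold()
  ae <- train_autoencoder(A, autoencoder_config(max_epochs = 5000, seed = 3))
  expect_gte(ae$report$r2, 0.97)
  # reconstruction never worse than the constant-mean predictor
  expect_lte(ae$report$mse, mean(scale(A, scale = FALSE)^2))
  # sigmoid output keeps decodings inside the unit cube
  dec <- decode(ae, matrix(runif(400, -1, 2.5), 100, 4))
  expect_true(all(dec >= 0 & dec <= 1))
  # training embeddings standardized to the documented span
  emb <- encode(ae, A)
  expect_equal(unname(apply(emb, 2, min)), rep(-0.75, 4), tolerance = 1e-9)
  expect_equal(unname(apply(emb, 2, max)), rep(2.25, 4), tolerance = 1e-9)
})

test_that("autoencoder training is deterministic and validates its inputs", {
  A <- affine_manifold(n = 120, seed = 2)
  cfg <- autoencoder_config(hidden = 6, max_epochs = 600, seed = 5)
  ae1 <- train_autoencoder(A, cfg)
  ae2 <- train_autoencoder(A, cfg)
  expect_identical(ae1$report, ae2$report)
  expect_identical(ae1$net$W, ae2$net$W)
  expect_error(train_autoencoder(A[1:4, ], cfg), "at least 8 rows")
  expect_error(train_autoencoder(A * 3, cfg), "normalized")
})

test_that("augmentation emits the requested number of in-range rows, reproducibly", {
  A <- affine_manifold(n = 200, seed = 6)
  ae <- train_autoencoder(A, autoencoder_config(hidden = 6, max_epochs = 800, seed = 6))
  aug <- augment(ae, n_samples = 500, seed = 7)
  expect_equal(nrow(aug), 500)
  expect_equal(ncol(aug), 6)
  expect_true(all(aug >= 0 & aug <= 1))
  expect_equal(attr(aug, "interval"), c(-1, 2.5))
  expect_identical(unclass(augment(ae, 500, seed = 7)), unclass(aug),
                   ignore_attr = TRUE)
  expect_false(identical(augment(ae, 500, seed = 8)[1, ], aug[1, ]))
  expect_error(augment(ae, 0, seed = 1), "n_samples")
})

test_that("autoencoder grid search picks the lowest-MSE configuration deterministically", {
  A <- affine_manifold(n = 150, seed = 9)
  single <- data.frame(hidden = 6, activation = "elu",
                       learning_rate = 0.03, decay = 0.8)
  s1 <- search_autoencoder(A, single, seed = 4, max_epochs = 400)
  expect_equal(s1$best$hidden, 6)
  expect_equal(s1$results$mse, s1$best_model$report$mse)

  grid <- data.frame(hidden = c(2, 16), activation = "elu",
                     learning_rate = 0.03, decay = 0.8)
  s2 <- search_autoencoder(A, grid, seed = 4, max_epochs = 800)
  expect_equal(min(s2$results$mse), s2$best_model$report$mse)
  s3 <- search_autoencoder(A, grid, seed = 4, max_epochs = 800)
  expect_identical(s2$results$mse, s3$results$mse)
  expect_error(search_autoencoder(A, data.frame(), seed = 1), "empty")
})

test_that("the predictor always has three hidden layers and handles a constant target", {
  set.seed(13)
  X <- matrix(runif(200), 50, 4)
  cfg <- predictor_config(neurons = c(4, 8, 4), max_epochs = 1500, seed = 2)
  p <- train_predictor(X, rep(0.37, 50), cfg)
  expect_length(p$net$W, 4)                  # 3 hidden + output
  expect_equal(p$net$sizes, c(4, 4, 8, 4, 1))
  expect_lte(p$report$mse, 0 + 1e-6)         # target variance is zero
  expect_error(predictor_config(neurons = c(4, 4)), "three hidden layers")
  p2 <- train_predictor(X, rep(0.37, 50), cfg)
  expect_identical(p$net$W, p2$net$W)        # seeded determinism
})

test_that("stronger l2 never improves the training fit", {
  set.seed(14)
  X <- matrix(runif(320), 80, 4)
  y <- plogis(2 * X[, 1] - X[, 2] + 0.5 * X[, 3] * X[, 4])
  weak <- train_predictor(X, y, predictor_config(l2 = 0.01, max_epochs = 1500, seed = 3))
  strong <- train_predictor(X, y, predictor_config(l2 = 1.0, max_epochs = 1500, seed = 3))
  expect_gte(strong$report$mse, weak$report$mse)
})

test_that("cross-validation partitions rows and rejects a sabotaged learning rate", {
  set.seed(15)
  X <- matrix(runif(600), 150, 4)
  y <- plogis(X %*% c(1.5, -1, 0.5, 0.25))[, 1]
  single <- data.frame(neurons = 5, activation = "elu",
                       learning_rate = 0.02, decay = 0.85)
  cv1 <- cross_validate_predictor(X, y, single, folds = 5, seed = 6, max_epochs = 300)
  expect_length(cv1$fold_id, 150)
  expect_setequal(unique(cv1$fold_id), 1:5)
  expect_equal(ncol(cv1$fold_mse), 5)
  expect_equal(cv1$best$neurons, rep(5, 3))

  grid <- data.frame(neurons = 5, activation = "elu",
                     learning_rate = c(0.02, 0.2), decay = 0.85)
  cv2 <- cross_validate_predictor(X, y, grid, folds = 3, seed = 6, max_epochs = 300)
  expect_equal(cv2$best$learning_rate, 0.02)
  expect_lte(min(cv2$results$mse), cv2$results$mse[2])
  expect_error(cross_validate_predictor(X, y, grid, folds = 1, seed = 1), "folds")
})

test_that("validation metrics behave for oracle and mean predictors", {
  set.seed(16)
  X <- matrix(runif(108), 27, 4)
  truth <- function(m) plogis(m %*% c(1, -2, 0.5, 1))[, 1]
  y <- truth(X)
  expect_equal(validate_on_original(truth, X, y)$r2, 1)
  expect_equal(validate_on_original(function(m) rep(mean(y), nrow(m)), X, y)$r2, 0)
})

test_that("non-finite training losses raise the divergence error", {
  net <- medopt:::mlp_new(c(2, 4, 1), c("relu", "linear"), seed = 1)
  X <- matrix(c(1e6, -1e6, 1e6, 1e6), 2, 2)
  expect_error(
    medopt:::mlp_train(net, X, matrix(c(1e8, -1e8)), epochs = 50,
                       learning_rate = 1e150),
    "divergence|non-finite")
})
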