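# DRSN training, prediction, and persistence.

test_that("zero-epoch training returns the initialized model unchanged", {
  d <- fixture_feature_task()
  cfg <- drsn_config(n_units = 1, channels = 4, epochs = 0, seed = 3)
  m1 <- train_drsn(cfg, d$x_train, train_y = d$y_train)
  m2 <- train_drsn(cfg, d$x_train, train_y = d$y_train)
  expect_identical(predict_force(m1, d$x_test), predict_force(m2, d$x_test))
  expect_equal(sum(!is.na(m1$history$train_loss)), 0)
})

test_that("training is deterministic given the seed", {
  d <- fixture_feature_task()
  cfg <- drsn_config(n_units = 1, channels = 4, epochs = 5, seed = 11)
  m1 <- train_drsn(cfg, d$x_train, d$x_val, d$y_train, d$y_val)
  m2 <- train_drsn(cfg, d$x_train, d$x_val, d$y_train, d$y_val)
  expect_identical(m1$history, m2$history)
  expect_identical(predict_force(m1, d$x_test), predict_force(m2, d$x_test))
})

test_that("a one-unit network learns the weighted-activation force map", {
  d <- fixture_feature_task()
  cfg <- drsn_config(n_units = 1, channels = 8, epochs = 30, seed = 42)
  model <- train_drsn(cfg, d$x_train, d$x_val, d$y_train, d$y_val)
  pred <- predict_force(model, d$x_val)
  expect_gt(cor(pred, d$y_val), 0.9)
  # validation MSE never ends above the untrained starting point
  h <- model$history
  expect_lte(min(h$val_mse[h$epoch > 0], na.rm = TRUE), h$val_mse[1])
  # beats the constant-mean predictor on the training set
  pred_tr <- predict_force(model, d$x_train)
  expect_lt(mse(d$y_train, pred_tr),
            mse(d$y_train, rep(mean(d$y_train), length(d$y_train))))
})

test_that("non-finite targets abort with the failing epoch named", {
  d <- fixture_feature_task()
  cfg <- drsn_config(n_units = 1, channels = 4, epochs = 2, seed = 1)
  y_bad <- d$y_train
  y_bad[1] <- NaN
  expect_error(train_drsn(cfg, d$x_train, train_y = y_bad), "epoch 1")
})

test_that("empty datasets are rejected for training, empty predict is empty", {
  cfg <- drsn_config(n_units = 1, channels = 4, epochs = 1)
  expect_error(train_drsn(cfg, array(0, c(0, 2, 3)), train_y = numeric(0)),
               "empty")
  d <- fixture_feature_task()
  model <- train_drsn(drsn_config(n_units = 1, channels = 4, epochs = 0),
                      d$x_train, train_y = d$y_train)
  expect_identical(predict_force(model, d$x_train[0, , , drop = FALSE]),
                   numeric(0))
})

test_that("checkpoint save/load reproduces predictions bit-identically", {
  d <- fixture_feature_task()
  cfg <- drsn_config(n_units = 1, channels = 4, epochs = 3, seed = 5)
  model <- train_drsn(cfg, d$x_train, train_y = d$y_train)
  path <- withr::local_tempfile(fileext = ".rds")
  drsn_save(model, path)
  model2 <- drsn_load(path)
  expect_identical(predict_force(model, d$x_test),
                   predict_force(model2, d$x_test))
})

test_that("matrix input is treated as a single-channel sequence", {
  set.seed(6)
  x <- matrix(rnorm(40 * 6), 40, 6)
  y <- x %*% c(1, 2, 0, 0, -1, 0.5)
  cfg <- drsn_config(n_units = 1, channels = 4, epochs = 2, seed = 6)
  model <- train_drsn(cfg, x, train_y = as.numeric(y))
  expect_length(predict_force(model, x), 40)
})
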