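test_that("hyper-parameters are validated against the declared grid", {
  expect_error(hyper_params("SGD"), "optimizer")
  expect_error(hyper_params(learning_rate = 5e-4), "learning_rate")
  expect_error(hyper_params(batch_size = 100), "batch_size")
  hp <- hyper_params("ADAM", 1e-3, 64, free = FALSE)
  expect_s3_class(hp, "hyper_params")
  expect_silent(hyper_params("ADAM", 7e-4, 100, free = TRUE))
})

test_that("training fits separable toy data and selects the best-val-loss epoch", {
  tr <- toy_features(60, seed = 1, prefix = "tr")
  va <- toy_features(20, seed = 2, prefix = "va")
  hp <- hyper_params("ADAM", 0.02, 16, epochs = 20, seed = 3, free = TRUE)
  m <- train_classifier(tr, va, hp, patience = 20)
  pred <- predict(m, tr)
  expect_equal(mean(pred == tr$y), 1.0)
  expect_equal(m$best_epoch, which.min(m$history$val_loss))
  expect_true(all(m$history$val_loss >= min(m$history$val_loss)))
})

test_that("softmax outputs are proper probabilities", {
  tr <- toy_features(30, seed = 4, n_classes = 3, prefix = "tr")
  va <- toy_features(10, seed = 5, n_classes = 3, prefix = "va")
  m <- train_classifier(tr, va, hyper_params("RMSprop", 1e-3, 64, epochs = 5,
                                             seed = 1))
  P <- attr(predict(m, va), "prob")
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))
})

test_that("training is deterministic and guards against leakage", {
  tr <- toy_features(30, seed = 6, prefix = "tr")
  va <- toy_features(10, seed = 7, prefix = "va")
  hp <- hyper_params("ADAM", 1e-3, 64, epochs = 5, seed = 11)
  m1 <- train_classifier(tr, va, hp)
  m2 <- train_classifier(tr, va, hp)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  expect_error(train_classifier(tr, tr, hp), "leakage")
})

test_that("grid search is exhaustive and consistent with its cells", {
  tr <- toy_features(40, seed = 8, prefix = "tr")
  va <- toy_features(15, seed = 9, prefix = "va")
  te <- toy_features(15, seed = 10, prefix = "te")

  full <- expand.grid(optimizer = c("ADAM", "RMSprop"),
                      learning_rate = c(1e-3, 1e-4, 1e-5),
                      batch_size = c(64, 128, 256))
  expect_equal(nrow(full), 18)  # cardinality of the declared grid

  # a one-cell grid equals a plain training call
  gs <- grid_search(tr, va, te,
                    grid = list(optimizer = "RMSprop",
                                learning_rate = 1e-4, batch_size = 128),
                    epochs = 8, seed = 2)
  expect_equal(nrow(gs$report), 1)
  plain <- train_classifier(tr, va, hyper_params("RMSprop", 1e-4, 128,
                                                 epochs = 8, seed = 2))
  expect_identical(gs$best_model$weights, plain$weights)

  # cells are ordered consistently with their validation losses
  gs2 <- grid_search(tr, va, te,
                     grid = list(optimizer = "ADAM",
                                 learning_rate = c(1e-3, 1e-5),
                                 batch_size = 64),
                     epochs = 10, seed = 2, selection = "validation")
  expect_equal(nrow(gs2$report), 2)
  best_row <- which.min(gs2$report$val_loss)
  expect_identical(gs2$best_hp$learning_rate,
                   gs2$report$learning_rate[best_row])
})

test_that("fine-tuning checks channel provenance and preserves performance on an identity channel", {
  tr <- toy_features(40, seed = 12, prefix = "tr")
  va <- toy_features(15, seed = 13, prefix = "va")
  te <- toy_features(15, seed = 14, prefix = "te")
  hp <- hyper_params("ADAM", 0.02, 16, epochs = 10, seed = 3, free = TRUE)
  base <- train_classifier(tr, va, hp)
  base_acc <- evaluate_model(base, te)$mAcc

  tr_id <- tr; tr_id$ir_name <- "reference"
  va_id <- va; va_id$ir_name <- "reference"
  ft <- fine_tune(base, tr_id, va_id)
  expect_equal(ft$ir_name, "reference")
  expect_equal(ft$base_ir_name, "reference")
  expect_lt(abs(evaluate_model(ft, te)$mAcc - base_acc), 0.05)

  va_other <- va; va_other$ir_name <- "tube"
  expect_error(fine_tune(base, tr_id, va_other), "channel mismatch")

  ft2 <- fine_tune(base, tr_id, va_id)
  expect_identical(ft$weights, ft2$weights)
})
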