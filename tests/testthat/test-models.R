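test_that("MLP-2 realises the published layer widths on 3-D input", {
  m <- build_model("MLP-2", 2, 3, seed = 1)
  dense <- Filter(function(l) l$type == "dense", m$layers)
  widths <- vapply(dense, function(l) ncol(l$W), 0L)
  expect_equal(widths, c(3L, 32L, 128L, 128L, 2L))
  expect_equal(nrow(dense[[1]]$W), 3L)
  expect_error(build_model("MLP-2", 2, 5, seed = 1),
               class = "ufm_invalid_argument")
})

test_that("initialisation is a pure function of the seed", {
  a <- build_model("MLP-2", 2, 3, seed = 7)
  b <- build_model("MLP-2", 2, 3, seed = 7)
  cc <- build_model("MLP-2", 2, 3, seed = 8)
  expect_identical(a$layers, b$layers)
  expect_false(identical(a$layers, cc$layers))
})

test_that("probability rows sum to one for untrained models", {
  m <- build_model("MLP-2", 2, 3, seed = 1)
  P <- predict_proba(m, matrix(rnorm(60), 20, 3))
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  expect_true(all(P >= 0))

  cm <- build_model("CNN-1", 3, list(modality = "image", side = 12), seed = 1)
  Pc <- predict_proba(cm, matrix(runif(2 * 144), 2, 144))
  expect_true(all(abs(rowSums(Pc) - 1) < 1e-6))
})

test_that("a degenerate schedule trains exactly one epoch", {
  tm <- generate_two_moons_3d(n = 100, seed = 1)
  cfg <- train_config(max_epochs = 1, patience = 0, seed = 1)
  fit <- train(build_model("MLP-2", 2, 3, seed = 1, config = cfg),
               tm$dataset, cfg)
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$best_epoch, 1)
})

test_that("training is bit-reproducible for a fixed seed and config", {
  tm <- generate_two_moons_3d(n = 200, seed = 5)
  cfg <- train_config(max_epochs = 8, patience = 8, seed = 9)
  f1 <- train(build_model("MLP-2", 2, 3, seed = 9, config = cfg),
              tm$dataset, cfg)
  f2 <- train(build_model("MLP-2", 2, 3, seed = 9, config = cfg),
              tm$dataset, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)
})

test_that("early stopping rolls back to the validation-loss minimum", {
  fx <- moons_fit()
  fit <- fx$fit
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
  # overrun past the best epoch is bounded by the patience
  expect_lte(nrow(fit$history) - fit$best_epoch, fx$config$patience)
  # the returned weights reproduce the recorded minimum validation loss
  va <- fx$data[fx$data$split == "val", ]
  P <- predict_proba(fit$model, va)
  val_loss <- -mean(log(P[cbind(seq_len(nrow(P)), va$label + 1L)]))
  expect_equal(val_loss, min(fit$history$val_loss), tolerance = 1e-6)
})

test_that("the reference task is learnable to high accuracy", {
  tm <- generate_two_moons_3d(n = 1000, carrier = FALSE, seed = 5)
  cfg <- train_config(seed = 3)
  fit <- train(build_model("MLP-2", 2, 3, seed = 3, config = cfg),
               tm$dataset, cfg)
  te <- tm$dataset[tm$dataset$split == "test", ]
  acc <- mean(max.col(predict_proba(fit$model, te)) - 1L == te$label)
  expect_gt(acc, 0.95)
})

test_that("corrupt input raises the divergence condition with its epoch", {
  tm <- generate_two_moons_3d(n = 100, seed = 1)
  tm$dataset$x[5] <- NaN
  err <- tryCatch(
    train(build_model("MLP-2", 2, 3, seed = 1), tm$dataset,
          train_config(max_epochs = 3, patience = 3, seed = 1)),
    condition = identity
  )
  expect_s3_class(err, "ufm_training_diverged")
  expect_match(conditionMessage(err), "epoch")
})

test_that("a missing validation split is rejected", {
  d <- tiny_tabular(n = 30, split = "train")
  expect_error(train(build_model("MLP-2", 2, 3, seed = 1), d,
                     train_config(seed = 1)),
               class = "ufm_invalid_argument")
})

test_that("regularisers modify training the way they should", {
  tm <- generate_two_moons_3d(n = 200, seed = 5)
  base <- train_config(max_epochs = 6, patience = 6, seed = 2)

  plain <- train(build_model("MLP-2", 2, 3, seed = 2, config = base),
                 tm$dataset, base)
  none <- train(build_model("MLP-2", 2, 3, seed = 2,
                            config = modify_cfg(base, "none", 0)),
                tm$dataset, modify_cfg(base, "none", 0))
  expect_identical(plain$history, none$history)

  drop0 <- modify_cfg(base, "dropout", 0)
  fd0 <- train(build_model("MLP-2", 2, 3, seed = 2, config = drop0),
               tm$dataset, drop0)
  expect_equal(fd0$history$val_loss, plain$history$val_loss,
               tolerance = 1e-12)

  wd <- modify_cfg(base, "weight_decay", 1e-2)
  fwd <- train(build_model("MLP-2", 2, 3, seed = 2, config = wd),
               tm$dataset, wd)
  l2 <- function(fit) sqrt(sum(unlist(lapply(fit$model$layers, function(l) {
    if (l$type == "dense") sum(l$W^2) else 0
  }))))
  expect_lte(l2(fwd), l2(plain))

  expect_error(build_model("MLP-2", 2, 3, seed = 1,
                           config = modify_cfg(base, "augmentation", 0)),
               class = "ufm_invalid_argument")

  # batch-norm and dropout insert layers
  bn <- build_model("MLP-2", 2, 3, seed = 1,
                    config = modify_cfg(base, "batch_norm", 0))
  expect_true(any(vapply(bn$layers, function(l) l$type, "") == "batchnorm"))
  dr <- build_model("MLP-2", 2, 3, seed = 1,
                    config = modify_cfg(base, "dropout", 0.25))
  expect_true(any(vapply(dr$layers, function(l) l$type, "") == "dropout"))
})
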