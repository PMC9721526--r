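test_that("soft Dice loss has its closed-form values", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(soft_dice_loss(t, t), 1e-6)
  expect_gt(soft_dice_loss(matrix(0, 2, 2), t), 1 - 1e-5)
  expect_equal(soft_dice_loss(0.5 * t, t), 1 / 3, tolerance = 1e-5)
  expect_error(soft_dice_loss(matrix(0, 2, 2), matrix(0, 2, 3)), "mismatch")
})

test_that("config validation fires", {
  expect_error(train_config(lambda = -1), "lambda")
  expect_error(train_config(patience = 0), "patience")
  expect_error(train_supervised(build_unet(2, 1, 2, 1), list()), "empty")
})

test_that("supervised training is reproducible and tracks its best", {
  w <- tiny_world()
  f1 <- train_supervised(w$net, w$ds$labelled, w$ds$val, w$cfg)
  f2 <- train_supervised(w$net, w$ds$labelled, w$ds$val, w$cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$predictor$params, f2$predictor$params)
  # best-so-far validation Dice is non-decreasing
  vd <- f1$history$val_dice[!is.na(f1$history$val_dice)]
  expect_true(all(diff(cummax(vd)) >= 0))
})

test_that("early stopping obeys the patience rule exactly", {
  w <- tiny_world()
  # with lr = 0 nothing ever beats the starting weights: every evaluation
  # is non-improving, so training stops after exactly `patience` of them
  # and the starting point is returned as best
  cfg <- train_config(epochs = 50, lr = 0, val_interval = 2, patience = 3,
                      seed = 1)
  fit <- train_supervised(w$net, w$ds$labelled, w$ds$val, cfg)
  expect_equal(fit$stopped_epoch, 3L * 2L)
  expect_equal(fit$best_epoch, 0L)
  expect_identical(fit$predictor$params, w$net$params)
})

test_that("lambda = 0 semi-supervision continues supervised training exactly", {
  w <- tiny_world()
  pre <- train_supervised(w$net, w$ds$labelled, w$ds$val,
                          train_config(epochs = 4, lr = 1e-3, val_interval = 2,
                                       patience = 5, seed = 1))
  cfg0 <- train_config(lambda = 0, epochs = 5, lr = 1e-3, val_interval = 2,
                       patience = 5, seed = 1)
  a <- train_semisupervised(pre$predictor, w$ds$labelled, w$ds$unlabelled,
                            w$ds$val, cfg = cfg0)
  b <- train_supervised(pre$predictor, w$ds$labelled, w$ds$val, cfg0)
  expect_identical(a$predictor$params, b$predictor$params)
  expect_identical(a$final_predictor$params, b$final_predictor$params)
})

test_that("an empty unlabelled set degenerates to supervised with a warning", {
  w <- tiny_world()
  expect_warning(
    fit <- train_semisupervised(w$net, w$ds$labelled, list(), w$ds$val,
                                cfg = w$cfg),
    "degenerating")
  expect_s3_class(fit, "topo_fit")
})

test_that("semi-supervised training logs both loss streams", {
  w <- tiny_world()
  cfg <- train_config(lambda = 0.01, epochs = 3, lr = 1e-4, val_interval = 2,
                      patience = 5, seed = 1)
  fit <- train_semisupervised(w$net, w$ds$labelled, w$ds$unlabelled[1:2],
                              w$ds$val, cfg = cfg)
  expect_true(all(is.finite(fit$history$dice_loss)))
  expect_true(all(is.finite(fit$history$topo_loss)))
})

test_that("post-processing with lambda = 0 is a no-op at the anchor", {
  w <- tiny_world()
  cfg <- train_config(lambda = 0, steps = 5, post_lr = 1e-2)
  ad <- postprocess_adapt(w$net, w$ds$test[[1]], topo_prior(c(1, 1)), cfg)
  expect_equal(ad$adapted, ad$anchor, tolerance = 1e-12)
  expect_true(all(ad$trace$total == 0))
})

test_that("post-processing never touches the original predictor", {
  w <- tiny_world()
  x <- w$ds$test[[1]]$image
  before <- predict(w$net, x)
  cfg <- train_config(lambda = 0.01, steps = 10, post_lr = 1e-2)
  ad <- postprocess_adapt(w$net, w$ds$test[[1]], topo_prior(c(1, 1)), cfg)
  expect_identical(predict(w$net, x), before)
  expect_false(identical(ad$adapted, before))
})

test_that("the adaptation objective decreases in the best-so-far sense", {
  w <- tiny_world()
  pre <- train_supervised(w$net, w$ds$labelled, w$ds$val,
                          train_config(epochs = 30, lr = 2e-3,
                                       val_interval = 5, patience = 5,
                                       seed = 2))
  cfg <- train_config(lambda = 0.01, steps = 40, post_lr = 1e-2)
  ad <- postprocess_adapt(pre$predictor, w$ds$test[[1]], topo_prior(c(1, 1)),
                          cfg)
  best <- cummin(ad$trace$total)
  expect_true(all(diff(best) <= 0))
  expect_lte(min(best), ad$trace$total[1])
  # and the run is reproducible
  ad2 <- postprocess_adapt(pre$predictor, w$ds$test[[1]], topo_prior(c(1, 1)),
                           cfg)
  expect_identical(ad$trace, ad2$trace)
  expect_identical(ad$adapted, ad2$adapted)
})
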