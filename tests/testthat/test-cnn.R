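# The conv regressor and its training protocol, on small fixtures: the
# mechanics (augmentation, determinism, fold bookkeeping, checkpoints) are
# exercised here; statistical performance at study scale lives in the
# acceptance suite.

test_that("augmentation: identity at zero magnitudes, exact integer shifts", {
  set.seed(15)
  vol <- array(rnorm(16^3), c(16, 16, 16))
  cfg0 <- tiny_config(max_translation = 0, max_rotation = 0)
  expect_identical(augment_volume(vol, cfg0, seed = 5), vol)

  # delta spike moved by a pure integer translation
  spike <- array(0, c(16, 16, 16))
  spike[8, 8, 8] <- 1
  moved <- augment_volume(spike, params = list(angle = 0, axis = 1,
                                               shift = c(2, -1, 3)))
  expect_equal(moved[10, 7, 11], 1)
  expect_equal(sum(moved), 1)
})

test_that("two 180-degree rotations about one axis restore the interior", {
  set.seed(16)
  smooth <- array(0, c(16, 16, 16))
  for (i in 1:16) for (j in 1:16) for (k in 1:16)
    smooth[i, j, k] <- sin(i / 4) + cos(j / 5) * k / 16
  once <- augment_volume(smooth, params = list(angle = 180, axis = 3,
                                               shift = c(0, 0, 0)))
  twice <- augment_volume(once, params = list(angle = 180, axis = 3,
                                              shift = c(0, 0, 0)))
  core <- 5:12
  expect_lt(max(abs(twice[core, core, core] - smooth[core, core, core])) /
              diff(range(smooth)), 1e-3)
})

test_that("training is deterministic and reduces the cost", {
  ts <- tiny_training_set(n = 24, seed = 7)
  cfg <- tiny_config(iterations = 15L, seed = 3L)
  m1 <- train_age_model(init_age_model(tiny_arch(), seed = 3), ts$X,
                        ts$ages, cfg)
  m2 <- train_age_model(init_age_model(tiny_arch(), seed = 3), ts$X,
                        ts$ages, cfg)
  expect_identical(m1$training_history, m2$training_history)
  expect_identical(predict_age(m1, ts$X), predict_age(m2, ts$X))
  expect_lt(tail(m1$training_history$mae, 1), m1$training_history$mae[1])
})

test_that("training loss is non-increasing in its trailing average", {
  ts <- tiny_training_set(n = 32, seed = 19)
  m <- train_age_model(init_age_model(tiny_arch(), seed = 2), ts$X, ts$ages,
                       tiny_config(iterations = 60L, seed = 2L))
  h <- m$training_history$mae
  trail <- stats::filter(h, rep(1 / 20, 20), sides = 1)
  trail <- trail[!is.na(trail)]
  # trailing-20 average never rises appreciably
  expect_lt(max(diff(trail)), 0.05 * trail[1])
})

test_that("the optimizer can overfit a tiny set (capacity check)", {
  ts <- tiny_training_set(n = 16, seed = 23)
  arch <- architecture_spec(input_shape = c(16L, 16L, 16L))
  cfg <- training_config(iterations = 2000L, batch_size = 4L,
                         augment = FALSE, seed = 5L)
  m <- train_age_model(init_age_model(arch, seed = 5), ts$X, ts$ages, cfg)
  expect_lt(mean(abs(predict_age(m, ts$X) - ts$ages)), 1)
})

test_that("an untrained model predicts a constant; prediction is deterministic", {
  arch <- tiny_arch()
  m <- init_age_model(arch, seed = 1)
  ts <- tiny_training_set(n = 4, seed = 31)
  p <- predict_age(m, ts$X)
  # zero-initialized head: prediction equals the head bias on any input
  expect_equal(p, rep(m$b_head * m$y_sd + m$y_mean, 4))
  expect_identical(predict_age(m, ts$X), p)
  expect_error(predict_age(m, matrix(0, 10, 2)), "input shape")
})

test_that("cross-validation folds partition the subjects evenly", {
  ts <- tiny_training_set(n = 40, seed = 27)
  cfg <- tiny_config(iterations = 2L, folds = 5L, batch_size = 4L)
  cv <- crossvalidate_age_model(ts$X, ts$ages, cfg, tiny_arch())
  expect_equal(length(cv$fold_mae), 5)
  expect_equal(as.vector(table(cv$assignments)), rep(8L, 5))
  expect_equal(cv$mean, mean(cv$fold_mae))
  expect_error(crossvalidate_age_model(ts$X[, 1:8], ts$ages[1:8], cfg,
                                       tiny_arch()),
               "folds")
})

test_that("checkpoints round-trip through JSON with identical predictions", {
  ts <- tiny_training_set(n = 16, seed = 29)
  m <- train_age_model(init_age_model(tiny_arch(), seed = 4), ts$X, ts$ages,
                       tiny_config(iterations = 5L, seed = 4L))
  path <- tempfile(fileext = ".json")
  save_age_model(m, path)
  m2 <- load_age_model(path)
  expect_equal(predict_age(m2, ts$X), predict_age(m, ts$X),
               tolerance = 1e-12)
  expect_equal(m2$training_history$mae, m$training_history$mae)
})

test_that("training rejects undersized batches and non-matching volumes", {
  ts <- tiny_training_set(n = 4, seed = 33)
  expect_error(train_age_model(init_age_model(tiny_arch()), ts$X, ts$ages,
                               tiny_config()),
               "batch_size")
  expect_error(train_age_model(init_age_model(architecture_spec()), ts$X,
                               ts$ages, tiny_config(batch_size = 2)),
               "input shape")
})
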