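test_that("model construction is seeded and softmax output is a probability triple", {
  cfg <- small_cnn_cfg()
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$conv[[1]]$W_, m2$conv[[1]]$W_)
  expect_identical(m1$fc1$W_, m2$fc1$W_)
  m3 <- build_model(small_cnn_cfg(seed = 99L))
  expect_false(identical(m1$conv[[1]]$W_, m3$conv[[1]]$W_))
  # untrained forward pass: probabilities sum to 1
  img <- small_hue_dataset(1)$images[[1]]
  p <- scopeflow:::cnn_forward(m1, scopeflow:::image_to_input(img, cfg))$probs
  expect_length(p, 3)
  expect_lt(abs(sum(p) - 1), 1e-6)
  expect_true(all(p >= 0))
})

test_that("training separates the hue-constructed classes and is deterministic", {
  ds <- small_hue_dataset(40)
  m <- train_model(build_model(small_cnn_cfg()), ds$images, ds$labels)
  expect_true(m$trained)
  expect_gte(m$meta$val_accuracy, 0.99)
  # training loss decreases over the first epochs of separable data (slow
  # learning rate so convergence spans several epochs)
  slow <- train_model(build_model(small_cnn_cfg(learning_rate = 0.001,
                                                n_epochs = 3L)),
                      ds$images, ds$labels)
  expect_gte(nrow(slow$log), 2)
  expect_lt(slow$log$train_loss[2], slow$log$train_loss[1])
  # two runs with the same seed agree exactly
  m2 <- train_model(build_model(small_cnn_cfg()), ds$images, ds$labels)
  expect_identical(m$log, m2$log)
  expect_identical(m$fc2$W_, m2$fc2$W_)
  # inference is deterministic and the class probabilities sum to 1
  pr <- predict_direction(m, ds$images[[1]])
  expect_identical(pr, predict_direction(m, ds$images[[1]]))
  expect_lt(abs(sum(pr$probs) - 1), 1e-6)
  expect_equal(pr$label, "insertion")
  expect_equal(pr$value, 1)
})

test_that("randomized hyperparameter search draws from the configured ranges", {
  ds <- small_hue_dataset(20)
  cfg <- small_cnn_cfg(n_search_draws = 4L, search_epochs = 1L, n_epochs = 4L)
  m <- train_model(build_model(cfg), ds$images, ds$labels)
  s <- m$meta$search
  expect_equal(nrow(s), 4)
  expect_true(all(s$lr >= 1e-7 & s$lr <= 1e-2))
  expect_true(all(s$momentum >= 0.8 & s$momentum <= 0.99))
  expect_true(all(s$l2 >= 1e-10 & s$l2 <= 1e-2))
  expect_equal(m$meta$learning_rate, s$lr[which.max(s$val_acc)])
})

test_that("label-shuffled training yields chance-level held-out accuracy", {
  ds <- small_hue_dataset(100)
  sh <- withr::with_seed(21, sample(ds$labels))
  tr <- 1:240; ho <- 241:300
  m <- train_model(build_model(small_cnn_cfg(n_epochs = 4L)),
                   ds$images[tr], sh[tr])
  acc <- mean(predict_directions(m, ds$images[ho]) == sh[ho])
  expect_lt(abs(acc - 1 / 3), 0.1)
})

test_that("cross-validation partitions samples exactly once and is reproducible", {
  ds <- small_hue_dataset(10, angle_jitter = 5)
  cfg <- small_cnn_cfg(n_epochs = 10L, batch_size = 8L)
  cm <- cross_validate(ds$images, ds$labels, cfg, k = 5)
  expect_equal(cm$total, 30)                       # every sample validated once
  expect_equal(unname(cm$column_sums), c(10, 10, 10))
  # separable-by-construction classes: no off-diagonal mass
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)
  cm2 <- cross_validate(ds$images, ds$labels, cfg, k = 5)
  expect_identical(cm$counts, cm2$counts)
})

test_that("degenerate training inputs are rejected", {
  ds <- small_hue_dataset(4)
  expect_error(train_model(build_model(small_cnn_cfg()), ds$images,
                           rep("insertion", length(ds$images))))
  expect_error(predict_direction(build_model(small_cnn_cfg()), ds$images[[1]]),
               "untrained")
  expect_error(cnn_config(learning_rate_range = c(1e-2, 1e-7)), "ordered")
  expect_error(cnn_config(dropout_rate = 1), "dropout")
  expect_error(cross_validate(ds$images[1:3], ds$labels[1:3],
                              small_cnn_cfg(), k = 5), "exceeds")
})
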