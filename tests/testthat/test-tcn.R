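test_that("configuration is validated: blocks, dropout, receptive field", {
  cfg <- tcn_config()
  expect_equal(cfg$n_blocks, 20L)
  expect_equal(cfg$dropout, 0.44)
  expect_gte(receptive_field(cfg), 100)
  # receptive field formula: 1 + sum((kernel - 1) * dilation)
  expect_equal(receptive_field(cfg), 1 + sum((cfg$kernel - 1) * cfg$dilations))

  expect_error(tcn_config(n_blocks = 0), class = "bafawubu_config_error")
  expect_error(tcn_config(dropout = 1), class = "bafawubu_config_error")
  expect_error(
    tcn_config(n_blocks = 2, dilations = c(1, 2)), # RF 7 < 100
    class = "bafawubu_config_error"
  )
  # automatic dilations always cover the window
  for (nb in c(1, 3, 4, 8, 20)) {
    expect_gte(receptive_field(tcn_config(n_blocks = nb)), 100)
  }
})

test_that("default architecture: 20 conv-bn-relu-dropout blocks, no residuals, single dense softmax head", {
  arch <- tcn_architecture(tcn_config())
  blocks <- arch[!is.na(arch$block), ]
  expect_equal(length(unique(blocks$block)), 20)
  expect_true(all(
    tapply(blocks$layer, blocks$block, paste, collapse = ">") ==
      "conv1d>batch_norm>relu>dropout"
  ))
  expect_false(any(arch$residual))
  head <- arch$layer[is.na(arch$block)]
  expect_equal(head, c("global_average_pool", "dense_softmax"))
  expect_equal(sum(arch$layer == "dense_softmax"), 1)
  expect_equal(arch$dropout[arch$layer == "dropout"], rep(0.44, 20))

  # parameter-group audit: kernel-tap weights + gamma + beta per block,
  # plus the dense head's weight and bias
  model <- build_tcn(tcn_config(n_blocks = 3, dilations = c(10, 20, 30)))
  expect_equal(length(model$params), 3 * (3 + 2) + 2)
})

test_that("splitting honours the 2/3 - 1/3 ratio, subject disjointness and the seed", {
  w <- small_dataset(3, reps = 1)
  w99 <- w[1:99]
  sp <- split_windows(w99, unit = "window", seed = 1)
  expect_equal(n_windows(sp$train), 66)
  expect_equal(n_windows(sp$validation), 33)

  sp_sub <- split_windows(w, unit = "subject", seed = 2)
  expect_length(
    intersect(unique(sp_sub$train$subject_id), unique(sp_sub$validation$subject_id)),
    0
  )
  sp_sub2 <- split_windows(w, unit = "subject", seed = 2)
  expect_identical(sp_sub$train$subject_id, sp_sub2$train$subject_id)

  no_ids <- w
  no_ids$subject_id <- NULL
  expect_error(split_windows(no_ids, unit = "subject"), "subject_id")
})

test_that("backpropagation matches finite-difference gradients", {
  # independent oracle: central finite differences on the training loss
  cfg <- tcn_config(
    n_blocks = 2, filters = 4, dilations = c(2, 3), dropout = 0,
    dense_units = 5, n_classes = 3, window_len = 8, seed = 3
  )
  model <- build_tcn(cfg, n_channels = 2, class_map = c("A", "B", "C"))
  set.seed(42)
  x <- array(rnorm(6 * 8 * 2), dim = c(6, 8, 2))
  y <- c(1L, 2L, 3L, 1L, 2L, 3L)
  step <- bafawubu:::tcn_train_step(model, x, y)
  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    bafawubu:::tcn_train_step(m2, x, y)$loss
  }
  eps <- 1e-5
  for (nm in c("blk1_W1", "blk2_W3", "blk1_gamma", "blk2_beta", "hid_W", "out_W", "out_b")) {
    p <- model$params[[nm]]
    for (k in sample(length(p), min(4, length(p)))) {
      up <- model$params
      dn <- model$params
      up[[nm]][k] <- p[k] + eps
      dn[[nm]][k] <- p[k] - eps
      numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(step$grads[[nm]][k], numeric_grad, tolerance = 1e-4)
    }
  }
})

test_that("predictions are normalized probabilities with argmax labels", {
  fit <- quick_fit()
  w <- standardize_windows(small_dataset(1))
  pred <- predict(fit, w)
  probs <- as.matrix(pred[, paste0(".prob_", bafa_codes())])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_true(all(pred$.pred_class %in% bafa_codes()))
  expect_equal(pred$.pred_class, bafa_codes()[max.col(probs)])

  bad <- w
  bad$x <- bad$x[, 1:50, , drop = FALSE]
  expect_error(predict(fit, bad), "samples")
})

test_that("training descends, is seed-deterministic, and learns separable data", {
  w <- standardize_windows(small_dataset(3, reps = 1))
  cfg <- tcn_config(
    n_blocks = 2, filters = 16, dilations = c(17, 33),
    dropout = 0.1, epochs = 60, seed = 7
  )
  fit1 <- fit_tcn(build_tcn(cfg), w, w)
  h <- tidy(fit1)
  expect_equal(nrow(h), 60)
  expect_lt(h$loss[60], h$loss[1])
  expect_true(all(is.finite(h$loss)))

  fit2 <- fit_tcn(build_tcn(cfg), w, w)
  expect_identical(tidy(fit1), tidy(fit2))

  # beats the majority-class baseline by a wide margin on separable data
  pred <- predict(fit1, w)
  acc <- mean(pred$.pred_class == w$label)
  majority <- max(table(w$label)) / n_windows(w)
  expect_gte(acc - majority, 0.5)

  relabeled <- w
  relabeled$label[1] <- "transition"
  expect_error(fit_tcn(build_tcn(cfg), relabeled), class = "bafawubu_data_error")
})

test_that("random search is seeded, returns the only config in a singleton space, and rejects divergent learning rates", {
  w <- standardize_windows(small_dataset(2, reps = 1))
  sp <- split_windows(w, unit = "window", seed = 3)
  base <- tcn_config(
    n_blocks = 2, filters = 8, dilations = c(17, 33),
    dropout = 0.1, epochs = 6, seed = 1
  )

  single <- tune_tcn(sp$train, sp$validation,
    space = list(dropout = 0.17),
    n_trials = 1, seed = 1, base_config = base
  )
  expect_equal(single$best_config$dropout, 0.17)

  t1 <- tune_tcn(sp$train, sp$validation,
    space = list(dropout = c(0, 0.5), learning_rate = c(1e-4, 1e-2)),
    n_trials = 3, seed = 5, base_config = base
  )
  t2 <- tune_tcn(sp$train, sp$validation,
    space = list(dropout = c(0, 0.5), learning_rate = c(1e-4, 1e-2)),
    n_trials = 3, seed = 5, base_config = base
  )
  expect_identical(t1$best_config, t2$best_config)
  expect_equal(nrow(t1$trials), 3)

  lr <- tune_tcn(sp$train, sp$validation,
    space = list(learning_rate = c(1e-3, 1e3)),
    n_trials = 4, seed = 2, base_config = base
  )
  expect_lt(lr$best_config$learning_rate, 1)

  expect_error(tune_tcn(sp$train, sp$validation, space = list(), n_trials = 2), "empty")
})

test_that("model bundles survive a JSON save/load round trip", {
  w <- standardize_windows(small_dataset(2, reps = 1))
  fit <- quick_fit(small_dataset(2, reps = 1), epochs = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_tcn(fit, path)
  fit2 <- load_tcn(path)
  expect_equal(fit2$config, fit$config)
  expect_identical(fit2$class_map, fit$class_map)
  p1 <- predict(fit, w)
  p2 <- predict(fit2, w)
  expect_identical(p1$.pred_class, p2$.pred_class)
  expect_equal(
    as.matrix(p1[, -1]), as.matrix(p2[, -1]),
    tolerance = 1e-12
  )
})
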