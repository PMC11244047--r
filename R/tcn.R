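#' Temporal convolutional network configuration
#'
#' The recognition network is a stack of `n_blocks` identical blocks --
#' dilated 1D convolution over time, batch normalization, ReLU, dropout --
#' with no residual connections, followed by global average pooling over
#' time and a dense softmax head over the seven movement classes. Defaults
#' follow the deployed recognizer: 20 blocks, dropout 0.44, 1000 epochs.
#'
#' Dilations default to a 1,2,4,8,16,32 cycle across blocks, scaled up by
#' the smallest integer factor that makes the receptive field cover the
#' window, so the configured stack always sees all 100 samples of a 2 s
#' window at 50 Hz.
#'
#' @param n_blocks number of convolutional blocks (default 20).
#' @param filters convolution filters per block (default 32).
#' @param kernel convolution kernel size (default 3).
#' @param dilations integer vector of per-block dilations, or `NULL` for the
#'   automatic cycle described above.
#' @param dropout dropout rate in `[0, 1)` (default 0.44).
#' @param dense_units neurons of an optional hidden fully connected ReLU
#'   layer between pooling and the softmax layer; 0 (default) means the
#'   softmax layer is the single dense head.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param epochs training epochs (default 1000).
#' @param batch_size minibatch size (default 64).
#' @param n_classes number of movement classes (7 for Bafa Wubu).
#' @param window_len samples per window the network must cover (default 100).
#' @param seed integer seed controlling initialization, shuffling and dropout.
#' @return A `tcn_config` list.
#' @export
tcn_config <- function(n_blocks = 20, filters = 32, kernel = 3,
                       dilations = NULL, dropout = 0.44, dense_units = 0,
                       learning_rate = 1e-3, epochs = 1000, batch_size = 64,
                       n_classes = 7, window_len = 100, seed = 1) {
  if (n_blocks < 1) rlang::abort("n_blocks must be >= 1", class = "bafawubu_config_error")
  if (dropout < 0 || dropout >= 1) {
    rlang::abort("dropout must lie in [0, 1)", class = "bafawubu_config_error")
  }
  if (learning_rate <= 0) rlang::abort("learning_rate must be positive", class = "bafawubu_config_error")
  if (is.null(dilations)) dilations <- auto_dilations(n_blocks, kernel, window_len)
  if (length(dilations) != n_blocks) {
    rlang::abort("dilations must have one entry per block", class = "bafawubu_config_error")
  }
  cfg <- structure(
    list(
      n_blocks = as.integer(n_blocks), filters = as.integer(filters),
      kernel = as.integer(kernel), dilations = as.integer(dilations),
      dropout = dropout, dense_units = as.integer(dense_units),
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), n_classes = as.integer(n_classes),
      window_len = as.integer(window_len), seed = as.integer(seed)
    ),
    class = "tcn_config"
  )
  rf <- receptive_field(cfg)
  if (rf < window_len) {
    rlang::abort(
      sprintf("receptive field (%d) smaller than the window (%d samples)", rf, window_len),
      class = "bafawubu_config_error"
    )
  }
  cfg
}

#' Default dilation scheme
#'
#' A 1,2,4,8,16,32 cycle across blocks (uncapped doubling over 20 blocks
#' would be astronomically dilated), scaled by the smallest integer factor
#' giving a receptive field of at least `window_len` samples.
#'
#' @param n_blocks number of blocks.
#' @param kernel kernel size.
#' @param window_len window length in samples.
#' @return Integer vector of per-block dilations.
#' @export
auto_dilations <- function(n_blocks, kernel = 3, window_len = 100) {
  base <- 2^((seq_len(n_blocks) - 1) %% 6)
  scale <- max(1, ceiling((window_len - 1) / ((kernel - 1) * sum(base))))
  as.integer(base * scale)
}

#' Receptive field of a configured stack
#'
#' `1 + sum((kernel - 1) * dilation_i)` input time steps influence one
#' output of the final block.
#'
#' @param config a [tcn_config()].
#' @return Integer receptive field in samples.
#' @export
receptive_field <- function(config) {
  as.integer(1 + (config$kernel - 1) * sum(config$dilations))
}

#' Build an untrained TCN
#'
#' Validates the configuration (receptive field must cover the window) and
#' initializes parameters with a seeded He-normal draw.
#'
#' @param config a [tcn_config()].
#' @param n_channels input channels (6 for a six-axis IMU).
#' @param class_map character vector mapping output index to class code.
#' @return An untrained `tcn_model`.
#' @export
build_tcn <- function(config, n_channels = 6, class_map = bafa_codes()) {
  stopifnot(inherits(config, "tcn_config"))
  if (length(class_map) != config$n_classes || anyDuplicated(class_map) > 0) {
    rlang::abort("class_map must list each of the classes exactly once",
      class = "bafawubu_config_error"
    )
  }
  params <- withr::with_seed(
    config$seed,
    init_tcn_params(config, n_channels, config$n_classes)
  )
  structure(
    list(
      config = config, params = params, bn = init_bn_state(config),
      class_map = class_map, n_channels = n_channels,
      channel_stats = NULL, history = NULL
    ),
    class = "tcn_model"
  )
}

#' Layer-by-layer architecture audit
#'
#' @param x a `tcn_model`, `tcn_fit` or [tcn_config()].
#' @return A tibble with one row per layer: `block`, `layer`, `filters`,
#'   `kernel`, `dilation`, `dropout`, `residual` (always `FALSE`: the stack
#'   has no skip connections).
#' @export
tcn_architecture <- function(x) {
  cfg <- if (inherits(x, "tcn_config")) x else x$config
  blocks <- purrr::map_dfr(seq_len(cfg$n_blocks), function(i) {
    tibble::tibble(
      block = i,
      layer = c("conv1d", "batch_norm", "relu", "dropout"),
      filters = cfg$filters,
      kernel = c(cfg$kernel, NA, NA, NA),
      dilation = c(cfg$dilations[i], NA, NA, NA),
      dropout = c(NA, NA, NA, cfg$dropout),
      residual = FALSE
    )
  })
  head_layers <- c(
    "global_average_pool",
    if (cfg$dense_units > 0) "dense_relu",
    "dense_softmax"
  )
  head <- tibble::tibble(
    block = NA_integer_, layer = head_layers,
    filters = c(cfg$filters, if (cfg$dense_units > 0) cfg$dense_units, cfg$n_classes),
    kernel = NA_real_, dilation = NA_real_, dropout = NA_real_, residual = FALSE
  )
  dplyr::bind_rows(blocks, head)
}

count_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Split a windowed dataset for training and validation
#'
#' Two-thirds training, one-third validation by default. With
#' `unit = "subject"` whole subjects are assigned to one side only,
#' preventing leakage of a subject's windows across the split; with
#' `unit = "window"` individual windows are shuffled.
#'
#' @param windows a labeled [imu_windows()] object.
#' @param train_frac training fraction (default 2/3).
#' @param unit `"subject"` (default; requires `subject_id`) or `"window"`.
#' @param seed integer seed for the shuffle.
#' @return A list with elements `train` and `validation`.
#' @export
split_windows <- function(windows, train_frac = 2 / 3,
                          unit = c("subject", "window"), seed = 1) {
  unit <- match.arg(unit)
  if (train_frac <= 0 || train_frac >= 1) rlang::abort("train_frac must lie in (0, 1)")
  m <- n_windows(windows)
  if (m == 0) rlang::abort("empty dataset")
  if (unit == "subject") {
    if (is.null(windows$subject_id)) {
      rlang::abort("subject-wise split requires subject_id")
    }
    subjects <- unique(windows$subject_id)
    shuffled <- withr::with_seed(seed, sample(subjects))
    n_train <- round(train_frac * length(subjects))
    n_train <- min(max(n_train, 1), length(subjects) - 1)
    train_sub <- shuffled[seq_len(n_train)]
    in_train <- windows$subject_id %in% train_sub
  } else {
    shuffled <- withr::with_seed(seed, sample.int(m))
    n_train <- round(train_frac * m)
    n_train <- min(max(n_train, 1), m - 1)
    in_train <- seq_len(m) %in% shuffled[seq_len(n_train)]
  }
  list(train = windows[in_train], validation = windows[!in_train])
}

labels_to_index <- function(labels, class_map) {
  idx <- match(labels, class_map)
  if (anyNA(idx)) {
    rlang::abort(
      paste0(
        "label(s) outside the class map: ",
        paste(unique(labels[is.na(idx)]), collapse = ", ")
      ),
      class = "bafawubu_data_error"
    )
  }
  idx
}

#' Train a TCN by minibatch Adam on cross-entropy
#'
#' Runs `config$epochs` epochs of seeded minibatch gradient descent,
#' recording per-epoch training loss, training accuracy and (when a
#' validation set is given) validation accuracy. Training is fully
#' deterministic given the configuration seed. If the loss becomes
#' non-finite (e.g. a divergent learning rate) training stops early.
#'
#' @param model an untrained `tcn_model` from [build_tcn()], or a
#'   [tcn_config()] (a model is built from it).
#' @param train labeled, standardized [imu_windows()] training set.
#' @param validation optional labeled validation set (standardized with the
#'   training statistics).
#' @param verbose print epoch progress.
#' @return A `tcn_fit`: the trained model with a `history` tibble
#'   (`epoch`, `loss`, `train_accuracy`, `validation_accuracy`).
#' @export
fit_tcn <- function(model, train, validation = NULL, verbose = FALSE) {
  if (inherits(model, "tcn_config")) model <- build_tcn(model)
  stopifnot(inherits(model, "tcn_model"))
  if (is.null(train$label)) rlang::abort("training windows must be labeled")
  cfg <- model$config
  y <- labels_to_index(train$label, model$class_map)
  x <- train$x
  m <- dim(x)[1]
  if (dim(x)[3] != model$n_channels) rlang::abort("channel count mismatch")
  model$channel_stats <- train$channel_stats
  y_val <- NULL
  if (!is.null(validation)) {
    y_val <- labels_to_index(validation$label, model$class_map)
  }
  batch <- min(cfg$batch_size, m)
  hist <- vector("list", cfg$epochs)
  opt <- adam_init(model$params)
  run_training <- function() {
    epochs_run <- 0
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(m)
      losses <- c()
      accs <- c()
      for (b0 in seq(1, m, by = batch)) {
        take <- ord[b0:min(b0 + batch - 1, m)]
        step <- tcn_train_step(model, x[take, , , drop = FALSE], y[take])
        if (!is.finite(step$loss)) {
          losses <- c(losses, step$loss)
          break
        }
        model$bn <<- step$bn
        up <- adam_update(model$params, step$grads, opt, cfg$learning_rate)
        model$params <<- up$params
        opt <<- up$state
        losses <- c(losses, step$loss)
        accs <- c(accs, step$accuracy)
      }
      val_acc <- NA_real_
      if (!is.null(validation) && all(is.finite(losses))) {
        pv <- tcn_forward_eval(model, validation$x)
        val_acc <- mean(max.col(pv) == y_val)
      }
      hist[[ep]] <<- tibble::tibble(
        epoch = ep, loss = mean(losses),
        train_accuracy = if (length(accs)) mean(accs) else NA_real_,
        validation_accuracy = val_acc
      )
      epochs_run <- ep
      if (verbose) {
        message(sprintf(
          "epoch %d: loss %.4f acc %.3f val %.3f",
          ep, mean(losses), mean(accs), val_acc
        ))
      }
      if (!all(is.finite(losses))) break
    }
    epochs_run
  }
  epochs_run <- withr::with_seed(cfg$seed + 1L, run_training())
  model$history <- dplyr::bind_rows(hist[seq_len(epochs_run)])
  class(model) <- c("tcn_fit", "tcn_model")
  model
}

#' Predict movement classes for windowed data
#'
#' @param object a trained `tcn_fit`.
#' @param windows an [imu_windows()] object with 100 x 6 windows. Raw
#'   (unstandardized) windows are standardized with the statistics stored in
#'   the fit; windows carrying their own `channel_stats` are used as-is.
#' @param ... unused.
#' @return A tibble with `.pred_class` and one `.prob_<code>` column per
#'   movement class; probabilities sum to 1 per window.
#' @export
predict.tcn_fit <- function(object, windows, ...) {
  stopifnot(inherits(windows, "imu_windows"))
  d <- dim(windows$x)
  if (d[2] != object$config$window_len || d[3] != object$n_channels) {
    rlang::abort(sprintf(
      "windows must be %d samples x %d channels",
      object$config$window_len, object$n_channels
    ))
  }
  if (is.null(windows$channel_stats) && !is.null(object$channel_stats)) {
    windows <- standardize_windows(windows, object$channel_stats)
  }
  prob <- tcn_forward_eval(object, windows$x)
  out <- tibble::tibble(.pred_class = object$class_map[max.col(prob)])
  colnames(prob) <- paste0(".prob_", object$class_map)
  dplyr::bind_cols(out, tibble::as_tibble(prob))
}

#' Per-epoch training history
#' @param x a `tcn_fit`.
#' @param ... unused.
#' @return The history tibble (`epoch`, `loss`, `train_accuracy`,
#'   `validation_accuracy`).
#' @export
tidy.tcn_fit <- function(x, ...) x$history

#' One-row fit summary
#' @param x a `tcn_fit` or `tcn_model`.
#' @param ... unused.
#' @return A one-row tibble: blocks, dropout, receptive field, parameter
#'   count, epochs run and final losses/accuracies.
#' @export
glance.tcn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_blocks = x$config$n_blocks,
    dropout = x$config$dropout,
    receptive_field = receptive_field(x$config),
    n_params = count_params(x),
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_train_accuracy = if (is.null(h)) NA_real_ else h$train_accuracy[nrow(h)],
    final_validation_accuracy = if (is.null(h)) NA_real_ else h$validation_accuracy[nrow(h)]
  )
}

#' @export
glance.tcn_model <- glance.tcn_fit

#' Plot training curves
#' @param object a `tcn_fit`.
#' @param ... unused.
#' @return A ggplot of loss and accuracies over epochs.
#' @export
autoplot.tcn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' @export
print.tcn_model <- function(x, ...) {
  cat(sprintf(
    "<%s: %d blocks (dropout %.2f), receptive field %d, %d parameters%s>\n",
    if (inherits(x, "tcn_fit")) "tcn_fit" else "tcn_model",
    x$config$n_blocks, x$config$dropout, receptive_field(x$config),
    count_params(x),
    if (!is.null(x$history)) sprintf(", %d epochs trained", nrow(x$history)) else ""
  ))
  invisible(x)
}

#' Seeded random hyperparameter search
#'
#' Samples `n_trials` configurations from the given bounds, trains each for
#' a short budget, and returns the configuration with the best final
#' validation accuracy. Trials whose loss diverges (non-finite) score
#' `-Inf`. The search is reproducible given `seed`.
#'
#' @param train,validation labeled standardized [imu_windows()] sets.
#' @param space named list of bounds: `n_blocks` and `dense_units` as
#'   integer `c(min, max)`, `dropout` as `c(min, max)`, `learning_rate` as
#'   `c(min, max)` sampled log-uniformly. A length-1 entry fixes the value.
#' @param n_trials number of sampled configurations (>= 1).
#' @param seed integer seed.
#' @param base_config [tcn_config()] supplying all non-searched fields.
#' @param epochs per-trial training budget.
#' @return A `tcn_tuning` list: `best_config`, `best_accuracy` and a
#'   `trials` tibble logging every configuration and score.
#' @export
tune_tcn <- function(train, validation, space, n_trials = 10, seed = 1,
                     base_config = tcn_config(n_blocks = 4, filters = 16, epochs = 30),
                     epochs = base_config$epochs) {
  if (is.null(space) || length(space) == 0) rlang::abort("empty search space")
  if (n_trials < 1) rlang::abort("n_trials must be >= 1")
  draw <- function(bounds, log_scale = FALSE, integer = FALSE) {
    if (length(bounds) == 1) return(rep(bounds, n_trials))
    lo <- min(bounds); hi <- max(bounds)
    u <- stats::runif(n_trials)
    v <- if (log_scale) exp(log(lo) + u * (log(hi) - log(lo))) else lo + u * (hi - lo)
    if (integer) round(v) else v
  }
  trials <- withr::with_seed(seed, tibble::tibble(
    trial = seq_len(n_trials),
    n_blocks = if ("n_blocks" %in% names(space)) draw(space$n_blocks, integer = TRUE) else base_config$n_blocks,
    dense_units = if ("dense_units" %in% names(space)) draw(space$dense_units, integer = TRUE) else base_config$dense_units,
    dropout = if ("dropout" %in% names(space)) draw(space$dropout) else base_config$dropout,
    learning_rate = if ("learning_rate" %in% names(space)) draw(space$learning_rate, log_scale = TRUE) else base_config$learning_rate
  ))
  score <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- tcn_config(
      n_blocks = trials$n_blocks[i], filters = base_config$filters,
      kernel = base_config$kernel, dropout = trials$dropout[i],
      dense_units = trials$dense_units[i],
      learning_rate = trials$learning_rate[i], epochs = epochs,
      batch_size = base_config$batch_size, seed = base_config$seed
    )
    fit <- fit_tcn(build_tcn(cfg), train, validation)
    va <- fit$history$validation_accuracy[nrow(fit$history)]
    score[i] <- if (is.finite(fit$history$loss[nrow(fit$history)]) && is.finite(va)) va else -Inf
  }
  trials$validation_accuracy <- ifelse(is.finite(score), score, NA_real_)
  best <- which.max(score)
  best_cfg <- tcn_config(
    n_blocks = trials$n_blocks[best], filters = base_config$filters,
    kernel = base_config$kernel, dropout = trials$dropout[best],
    dense_units = trials$dense_units[best],
    learning_rate = trials$learning_rate[best], epochs = base_config$epochs,
    batch_size = base_config$batch_size, seed = base_config$seed
  )
  structure(
    list(best_config = best_cfg, best_accuracy = score[best], trials = trials),
    class = "tcn_tuning"
  )
}

#' Save a trained model as a JSON bundle
#'
#' Serializes configuration, class map, channel statistics, batchnorm
#' running statistics and all weights (full precision) to a single JSON
#' file; [load_tcn()] restores a fit whose predictions match the original.
#'
#' @param fit a `tcn_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_tcn <- function(fit, path) {
  payload <- list(
    config = unclass(fit$config),
    class_map = fit$class_map,
    n_channels = fit$n_channels,
    channel_stats = fit$channel_stats,
    bn = fit$bn,
    params = lapply(fit$params, function(p) {
      list(dim = if (is.matrix(p)) dim(p) else length(p), value = as.vector(p))
    }),
    history = fit$history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model bundle written by [save_tcn()]
#'
#' @param path JSON bundle path.
#' @return A `tcn_fit`.
#' @export
load_tcn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- tcn_config(
    n_blocks = cfg$n_blocks, filters = cfg$filters, kernel = cfg$kernel,
    dilations = cfg$dilations, dropout = cfg$dropout,
    dense_units = cfg$dense_units, learning_rate = cfg$learning_rate,
    epochs = cfg$epochs, batch_size = cfg$batch_size,
    n_classes = cfg$n_classes, window_len = cfg$window_len, seed = cfg$seed
  )
  params <- lapply(payload$params, function(p) {
    if (length(p$dim) == 2) matrix(p$value, p$dim[1], p$dim[2]) else p$value
  })
  # jsonlite simplifies a list of equal-length vectors to a matrix
  unpack_rows <- function(x) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else x
  }
  bn <- list(
    run_mean = unpack_rows(payload$bn$run_mean),
    run_var = unpack_rows(payload$bn$run_var)
  )
  structure(
    list(
      config = config, params = params, bn = bn,
      class_map = payload$class_map, n_channels = payload$n_channels,
      channel_stats = if (is.null(payload$channel_stats)) NULL else tibble::as_tibble(payload$channel_stats),
      history = if (is.null(payload$history)) NULL else tibble::as_tibble(payload$history)
    ),
    class = c("tcn_fit", "tcn_model")
  )
}
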