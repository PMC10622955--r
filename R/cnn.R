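# The 3D convolutional age regressor. The published training protocol is
# followed exactly (MAE cost, SGD with lr 0.001, momentum 0.1, inverse-time
# lr decay 5e-5 per optimizer step, batch size 8, 150 iterations, on-the-fly
# translation/rotation augmentation, 5-fold cross-validation); the layer
# layout itself is a configurable stand-in sized for desk-scale grids.
# Targets are standardized internally (the head predicts z-scored age and the
# model stores the training mean/SD), a standard regression normalization
# that keeps the fixed small learning rate workable at any age scale.

#' Training configuration for the age regressor
#'
#' Defaults are the published protocol. `iterations` counts passes over the
#' training set (epochs); `iteration_unit` records that reading and accepts
#' `"steps"` to count optimizer updates instead.
#'
#' @param learning_rate,momentum,lr_decay SGD hyperparameters; the learning
#'   rate at optimizer step t is `lr / (1 + lr_decay * t)`.
#' @param batch_size Mini-batch size.
#' @param iterations Training duration (see `iteration_unit`).
#' @param iteration_unit `"epochs"` (default) or `"steps"`.
#' @param folds Cross-validation folds.
#' @param max_translation Augmentation: maximal voxel shift per axis.
#' @param max_rotation Augmentation: maximal rotation in degrees about a
#'   random axis.
#' @param augment Enable on-the-fly augmentation during training.
#' @param clip_norm Optional global gradient-norm clip per batch (0, the
#'   default, disables it).
#' @param loss Cost function; only `"mae"` (mean absolute error) is supported.
#' @param seed Integer seed for init, shuffling and augmentation draws.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, momentum = 0.1,
                            lr_decay = 5e-5, batch_size = 8L,
                            iterations = 150L,
                            iteration_unit = c("epochs", "steps"),
                            folds = 5L, max_translation = 2,
                            max_rotation = 10, augment = TRUE,
                            clip_norm = 0, loss = "mae", seed = 1L) {
  iteration_unit <- match.arg(iteration_unit)
  stopifnot(learning_rate > 0, momentum >= 0, lr_decay >= 0,
            batch_size >= 1, iterations >= 1, folds >= 2,
            max_translation >= 0, max_rotation >= 0, clip_norm >= 0,
            identical(loss, "mae"))
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 iteration_unit = iteration_unit, folds = as.integer(folds),
                 max_translation = max_translation,
                 max_rotation = max_rotation, augment = isTRUE(augment),
                 clip_norm = clip_norm, loss = loss,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Architecture of the 3D convolutional regressor
#'
#' A stack of 3D conv blocks (ReLU activations, zero padding, configurable
#' stride) followed by global average pooling and a linear scalar head
#' (years). The default - four stride-2 blocks of 8, 16, 32 and 64 filters
#' with 3^3 kernels (downsampling fused into the convolutions) - is sized
#' for 32^3 desk-scale phantoms; a wide final stage speeds up the fixed
#' small-learning-rate head fit, whose output range grows with the channel
#' count.
#'
#' @param conv_blocks data.frame with columns `filters`, `kernel` (odd),
#'   `stride`, one row per block.
#' @param activation Only `"relu"` is implemented.
#' @param input_shape Integer length-3 grid the model expects.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(conv_blocks = data.frame(
                                filters = c(8L, 16L, 32L, 64L),
                                kernel = 3L,
                                stride = 2L),
                              activation = "relu",
                              input_shape = c(32L, 32L, 32L)) {
  stopifnot(identical(activation, "relu"),
            all(c("filters", "kernel", "stride") %in% names(conv_blocks)),
            nrow(conv_blocks) >= 1,
            all(conv_blocks$kernel %% 2 == 1),
            all(conv_blocks$stride >= 1), all(conv_blocks$filters >= 1),
            length(input_shape) == 3)
  structure(list(conv_blocks = conv_blocks, activation = activation,
                 input_shape = as.integer(input_shape)),
            class = "architecture_spec")
}

blocks_matrix <- function(arch) {
  matrix(as.integer(c(arch$conv_blocks$filters, arch$conv_blocks$kernel,
                      arch$conv_blocks$stride)),
         ncol = 3, dimnames = list(NULL, c("filters", "kernel", "stride")))
}

#' Initialize an untrained age model
#'
#' He-normal initialization for the conv weights; the linear head starts at
#' zero so the untrained model predicts the training-mean age exactly and the
#' early optimization is head-first. The feature/target standardization
#' constants default to identity and are set by [train_age_model()].
#'
#' @param arch An [architecture_spec()].
#' @param seed Integer seed for the weight draw.
#' @return An object of class `age_model`.
#' @export
init_age_model <- function(arch = architecture_spec(), seed = 1L) {
  bl <- arch$conv_blocks
  with_seed(seed, {
    c_in <- 1L
    W <- list(); b <- list()
    for (l in seq_len(nrow(bl))) {
      fan_in <- c_in * bl$kernel[l]^3
      W[[l]] <- matrix(rnorm(fan_in * bl$filters[l], 0, sqrt(2 / fan_in)),
                       fan_in, bl$filters[l])
      b[[l]] <- rep(0, bl$filters[l])
      c_in <- bl$filters[l]
    }
    w_head <- rep(0, c_in)
    structure(list(architecture = arch, W = W, b = b, w_head = w_head,
                   b_head = 0, feat_mean = rep(0, c_in),
                   feat_sd = rep(1, c_in), y_mean = 0, y_sd = 1,
                   training_history = data.frame(iteration = integer(),
                                                 mae = numeric())),
              class = "age_model")
  })
}

#' @export
print.age_model <- function(x, ...) {
  trained <- nrow(x$training_history) > 0
  cat("<age_model> ", nrow(x$architecture$conv_blocks), " conv blocks (",
      paste(x$architecture$conv_blocks$filters, collapse = "-"),
      " filters), input ", paste(x$architecture$input_shape, collapse = "x"),
      if (trained) sprintf("; trained, final MAE %.2f y",
                           utils::tail(x$training_history$mae, 1))
      else "; untrained", "\n", sep = "")
  invisible(x)
}

#' On-the-fly training augmentation
#'
#' Applies a random rigid perturbation to an intensity volume: a uniform
#' voxel shift up to `max_translation` per axis and a rotation up to
#' `max_rotation` degrees about one randomly chosen axis, trilinearly
#' resampled (label maps are never augmented). With both magnitudes 0 the
#' volume is returned unchanged.
#'
#' @param volume Numeric 3D array.
#' @param config A [training_config()] (magnitudes are read from it).
#' @param seed Integer seed for the perturbation draw.
#' @param params Optional explicit list `(angle, axis, shift)` overriding the
#'   random draw (`axis` in 1:3, `shift` length-3 voxels, `angle` degrees).
#' @return Numeric 3D array of the same shape.
#' @export
augment_volume <- function(volume, config = training_config(), seed = 1L,
                           params = NULL) {
  if (is.null(params)) {
    if (config$max_translation == 0 && config$max_rotation == 0)
      return(volume)
    params <- with_seed(seed, list(
      axis = sample.int(3, 1),
      angle = runif(1, -config$max_rotation, config$max_rotation),
      shift = runif(3, -config$max_translation, config$max_translation)))
  }
  cpp_rigid_transform(as.numeric(volume), dim(volume), params$angle,
                      params$axis - 1L, params$shift[1], params$shift[2],
                      params$shift[3])
}

# Stack preprocessed volumes into the (n_voxels x n_subjects) matrix the C++
# core consumes.
volumes_to_matrix <- function(volumes) {
  if (is.list(volumes))
    volumes <- vapply(volumes, as.numeric, numeric(length(volumes[[1]])))
  volumes
}

#' Train the age regressor
#'
#' Runs the SGD/MAE protocol of the [training_config()] on preprocessed
#' volumes. Ages are standardized internally; `training_history` records the
#' running training MAE per epoch in years. Two runs with the same seed are
#' identical.
#'
#' @param model An [init_age_model()] (or a trained one, to continue).
#' @param volumes List of preprocessed 3D arrays, or a (voxels x n) matrix.
#' @param ages Numeric vector of target ages (years).
#' @param config A [training_config()].
#' @return The trained `age_model` with updated weights and history.
#' @export
train_age_model <- function(model, volumes, ages,
                            config = training_config()) {
  X <- volumes_to_matrix(volumes)
  stopifnot(ncol(X) == length(ages), length(ages) >= config$batch_size)
  arch <- model$architecture
  if (nrow(X) != prod(arch$input_shape))
    stop("volume size does not match the architecture's input shape",
         call. = FALSE)
  y_mean <- mean(ages); y_sd <- sd(ages)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  epochs <- if (config$iteration_unit == "epochs") config$iterations
            else max(1L, ceiling(config$iterations * config$batch_size /
                                 length(ages)))
  fit <- cpp_cnn_train(X, (ages - y_mean) / y_sd, arch$input_shape,
                       blocks_matrix(arch), model$W, model$b, model$w_head,
                       model$b_head, config$learning_rate, config$momentum,
                       config$lr_decay, config$batch_size, epochs,
                       config$max_translation, config$max_rotation,
                       config$augment,
                       substream_seed(config$seed, "training"),
                       config$clip_norm)
  model$W <- fit$W; model$b <- fit$b
  model$w_head <- as.numeric(fit$w_head); model$b_head <- fit$b_head
  model$feat_mean <- as.numeric(fit$feat_mean)
  model$feat_sd <- as.numeric(fit$feat_sd)
  model$y_mean <- y_mean; model$y_sd <- y_sd
  model$training_history <- rbind(
    model$training_history,
    data.frame(iteration = nrow(model$training_history) +
                 seq_along(fit$history),
               mae = fit$history * y_sd))
  model
}

#' Predict age from preprocessed volumes
#'
#' Deterministic evaluation-mode forward pass (no test-time augmentation).
#'
#' @param model A trained `age_model`.
#' @param volumes A single 3D array, a list of them, or a (voxels x n) matrix.
#' @return Numeric vector of predicted ages (years).
#' @export
predict_age <- function(model, volumes) {
  if (is.array(volumes) && length(dim(volumes)) == 3)
    volumes <- list(volumes)
  X <- volumes_to_matrix(volumes)
  arch <- model$architecture
  if (nrow(X) != prod(arch$input_shape))
    stop("volume size does not match the architecture's input shape",
         call. = FALSE)
  z <- cpp_cnn_predict(X, arch$input_shape, blocks_matrix(arch), model$W,
                       model$b, model$w_head, model$b_head,
                       matrix(model$feat_mean, 1), matrix(model$feat_sd, 1))
  as.numeric(z) * model$y_sd + model$y_mean
}

#' K-fold cross-validation of the training protocol
#'
#' Deterministic fold assignment from the config seed; every subject is
#' out-of-fold exactly once. Reports the per-fold out-of-fold MAE.
#'
#' @param volumes List of preprocessed 3D arrays or a (voxels x n) matrix.
#' @param ages Numeric vector of ages.
#' @param config A [training_config()].
#' @param arch An [architecture_spec()].
#' @return List: `fold_mae` (years, length `folds`), `mean`, `sd`,
#'   `assignments` (fold index per subject).
#' @export
crossvalidate_age_model <- function(volumes, ages,
                                    config = training_config(),
                                    arch = architecture_spec()) {
  X <- volumes_to_matrix(volumes)
  n <- length(ages)
  if (n < config$folds * config$batch_size)
    stop("need at least folds * batch_size subjects", call. = FALSE)
  folds <- with_seed(substream_seed(config$seed, "folds"),
                     sample(rep_len(seq_len(config$folds), n)))
  fold_mae <- numeric(config$folds)
  for (f in seq_len(config$folds)) {
    tr <- folds != f
    model <- init_age_model(arch, seed = substream_seed(config$seed,
                                                        "training", f))
    model <- train_age_model(model, X[, tr, drop = FALSE], ages[tr], config)
    pred <- predict_age(model, X[, !tr, drop = FALSE])
    fold_mae[f] <- mean(abs(pred - ages[!tr]))
  }
  list(fold_mae = fold_mae, mean = mean(fold_mae), sd = sd(fold_mae),
       assignments = folds)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON archive holding the architecture, weights, target
#' standardization constants and training history.
#'
#' @param model An `age_model`.
#' @param path Checkpoint path (.json).
#' @return `load_age_model` returns the restored `age_model`.
#' @export
save_age_model <- function(model, path) {
  payload <- list(
    architecture = list(conv_blocks = model$architecture$conv_blocks,
                        activation = model$architecture$activation,
                        input_shape = model$architecture$input_shape),
    W = lapply(model$W, as.matrix), b = model$b,
    w_head = model$w_head, b_head = model$b_head,
    feat_mean = model$feat_mean, feat_sd = model$feat_sd,
    y_mean = model$y_mean, y_sd = model$y_sd,
    training_history = model$training_history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_age_model
#' @export
load_age_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- architecture_spec(as.data.frame(p$architecture$conv_blocks),
                            p$architecture$activation,
                            p$architecture$input_shape)
  structure(list(architecture = arch,
                 W = lapply(p$W, function(w) matrix(unlist(w), nrow = nrow(w))),
                 b = lapply(seq_len(nrow(arch$conv_blocks)),
                            function(l) as.numeric(p$b[[l]])),
                 w_head = as.numeric(p$w_head), b_head = p$b_head,
                 feat_mean = as.numeric(p$feat_mean),
                 feat_sd = as.numeric(p$feat_sd),
                 y_mean = p$y_mean, y_sd = p$y_sd,
                 training_history = as.data.frame(p$training_history)),
            class = "age_model")
}
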