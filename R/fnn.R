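# Paired stage classifiers: a no-memory FNN on the 37 EEG features and a
# memory-augmented FNN that appends the K-dimensional transition vector.

#' Training configuration for the stage classifiers
#'
#' Defaults follow the reference training regime: three ReLU hidden layers
#' of 128, 64 and 32 units, softmax output over K = 5 stages, Adam with
#' learning rate 0.001, sparse categorical cross-entropy, early stopping
#' with patience 10 on a 10% row-wise validation split.
#'
#' @param hidden_sizes Hidden layer widths.
#' @param n_classes Number of stages K.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param val_fraction Validation fraction (0 < f < 0.5).
#' @param scale_memory_inputs Pass the transition vector through the
#'   feature scaler as well (default `FALSE`: transition vectors are
#'   already probabilities in `[0, 1]`).
#' @param seed Integer seed.
#' @return Object of class `"fnn_config"`.
#' @export
fnn_config <- function(hidden_sizes = c(128L, 64L, 32L), n_classes = 5L,
                       learning_rate = 1e-3, patience = 10L,
                       max_epochs = 100L, batch_size = 128L,
                       val_fraction = 0.1, scale_memory_inputs = FALSE,
                       seed = 1L) {
  stopifnot(length(hidden_sizes) >= 1, val_fraction > 0, val_fraction < 0.5)
  structure(
    list(hidden_sizes = as.integer(hidden_sizes),
         n_classes = as.integer(n_classes),
         learning_rate = learning_rate, patience = as.integer(patience),
         max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), val_fraction = val_fraction,
         scale_memory_inputs = scale_memory_inputs, seed = as.integer(seed)),
    class = "fnn_config"
  )
}

#' Fit a per-feature standardizing scaler
#'
#' Column means and (population) standard deviations, fitted on training
#' rows only. Zero-dispersion columns get SD 1 with a warning.
#'
#' @param x Numeric training matrix (>= 2 rows).
#' @return List with `mean` and `sd` vectors, class `"feature_scaler"`.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2L)
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-dispersion column(s); SD set to 1")
    sdv[sdv == 0] <- 1
  }
  structure(list(mean = mu, sd = sdv), class = "feature_scaler")
}

#' Apply a fitted scaler
#'
#' @param scaler A [fit_scaler()] result.
#' @param x Matrix with the same columns as the training matrix.
#' @return Standardized matrix.
#' @export
apply_scaler <- function(scaler, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(scaler$mean)) {
    stop("input width ", ncol(x), " does not match scaler width ",
         length(scaler$mean))
  }
  sweep(sweep(x, 2L, scaler$mean), 2L, scaler$sd, `/`)
}

#' Transition-vector memory inputs for training
#'
#' Row t is the transition vector computed from the one-hot encoding of the
#' previous epoch's true label: `onehot(label[t-1]) %*% T`, i.e. the row of
#' `T` indexed by the previous true stage. The first epoch uses the wake
#' prior (`onehot(W) %*% T`). Labels must come from a single subject;
#' memory never crosses subject boundaries.
#'
#' @param labels One subject's time-ordered stage labels.
#' @param T A [transition_matrix()].
#' @return Matrix with `length(labels)` rows and K columns, each row a
#'   probability vector.
#' @export
assemble_memory_inputs_train <- function(labels, T) {
  T <- as_transition_matrix(T)
  stages <- rownames(T)
  labels <- check_stage_labels(labels, stages)
  prev <- c("W", labels[-length(labels)])
  unclass(T)[match(prev, stages), , drop = FALSE]
}

#' Train one stage classifier
#'
#' Fits the scaler on the given (training) feature rows, standardizes,
#' optionally appends memory inputs, and trains the MLP. The memory model
#' is obtained by supplying `memory_inputs` (input width 37 + K); the
#' no-memory model by omitting them.
#'
#' @param features Matrix or data.frame of the 37 epoch features
#'   (training subjects only).
#' @param labels Stage labels aligned with the feature rows.
#' @param config An [fnn_config()].
#' @param memory_inputs Optional matrix of transition vectors (same row
#'   count, K columns), as from [assemble_memory_inputs_train()].
#' @param stage_order Ordered stage set defining the output units.
#' @return Object of class `"stager_fnn"`.
#' @export
train_stage_model <- function(features, labels, config = fnn_config(),
                              memory_inputs = NULL,
                              stage_order = sleep_stages()) {
  features <- as.matrix(features)
  labels <- check_stage_labels(labels, stage_order)
  stopifnot(nrow(features) == length(labels))
  absent <- setdiff(stage_order, unique(labels))
  if (length(absent) > 0L) {
    warning("class(es) absent from training labels: ",
            paste(absent, collapse = ", "))
  }
  y <- match(labels, stage_order)
  scaler <- fit_scaler(features)
  x <- apply_scaler(scaler, features)
  memory_mode <- !is.null(memory_inputs)
  if (memory_mode) {
    memory_inputs <- as.matrix(memory_inputs)
    stopifnot(nrow(memory_inputs) == nrow(x),
              ncol(memory_inputs) == length(stage_order))
    if (isTRUE(config$scale_memory_inputs)) {
      mem_scaler <- fit_scaler(memory_inputs)
      memory_inputs <- apply_scaler(mem_scaler, memory_inputs)
    }
    x <- cbind(x, memory_inputs)
  }
  net <- mlp_fit(x, y, n_classes = config$n_classes,
                 hidden = config$hidden_sizes, lr = config$learning_rate,
                 batch_size = config$batch_size,
                 max_epochs = config$max_epochs, patience = config$patience,
                 val_fraction = config$val_fraction, seed = config$seed)
  structure(
    list(net = net, scaler = scaler, stage_order = stage_order,
         memory_mode = memory_mode, config = config),
    class = "stager_fnn"
  )
}

#' @export
print.stager_fnn <- function(x, ...) {
  cat(sprintf(
    "<stager_fnn> %s model: input %d -> %s -> softmax(%d); best epoch %d, val loss %.4f\n",
    if (x$memory_mode) "memory" else "no-memory", x$net$sizes[1L],
    paste(x$config$hidden_sizes, collapse = "-"), x$config$n_classes,
    x$net$best_epoch, x$net$val_loss))
  invisible(x)
}

#' Predict stage probabilities
#'
#' @param object A `"stager_fnn"`.
#' @param features Feature matrix (37 columns, raw scale; the stored
#'   scaler is applied).
#' @param memory_inputs Transition-vector matrix; required iff the model
#'   was trained in memory mode.
#' @param ... Unused.
#' @return Matrix of softmax probabilities with stage column names.
#' @export
predict.stager_fnn <- function(object, features, memory_inputs = NULL, ...) {
  x <- apply_scaler(object$scaler, as.matrix(features))
  if (object$memory_mode) {
    if (is.null(memory_inputs)) stop("memory model requires memory_inputs")
    x <- cbind(x, as.matrix(memory_inputs))
  } else if (!is.null(memory_inputs)) {
    stop("no-memory model takes no memory_inputs")
  }
  p <- mlp_predict(object$net, x)
  dimnames(p) <- list(NULL, object$stage_order)
  p
}

#' Strictly causal sequential prediction with memory
#'
#' Iterates one subject's epochs in time order. The memory input of epoch t
#' is the previous epoch's *predicted* softmax distribution propagated
#' through `T` (`v_t = p_hat_{t-1} %*% T`); the first epoch uses the wake
#' prior. The output at epoch t therefore depends only on epochs up to t —
#' no ground-truth labels and no future epochs are used.
#'
#' @param model A memory-mode `"stager_fnn"`.
#' @param features Time-ordered feature matrix of one subject.
#' @param T A [transition_matrix()].
#' @return Matrix of per-epoch softmax probabilities.
#' @export
sequential_predict_memory <- function(model, features, T) {
  stopifnot(inherits(model, "stager_fnn"), model$memory_mode)
  T <- as_transition_matrix(T)
  features <- as.matrix(features)
  n <- nrow(features)
  K <- nrow(T)
  out <- matrix(NA_real_, n, K, dimnames = list(NULL, model$stage_order))
  p_prev <- initial_distribution(model$stage_order)
  for (t in seq_len(n)) {
    v <- transition_vector(p_prev, T)
    out[t, ] <- predict(model, features[t, , drop = FALSE],
                        memory_inputs = matrix(v, 1L))
    p_prev <- out[t, ]
  }
  out
}
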