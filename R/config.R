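#' Model configuration
#'
#' Hyperparameters of the multinomial-convolution network. Defaults are the
#' architecture that won the original 10-fold cross-validated search on the
#' 2,440-sequence HepG2 liver-enhancer MPRA dataset: 512 kernels of length
#' 12, ReLU activation, max pooling, dropout 0.4, a single-node fully
#' connected layer, batch size 64, learning rate 0.001 and L2 factor 0.001.
#' The softmax temperature `alpha` was searched over 100-140; the default
#' here is the midpoint 120 and `alpha` is a fixed (not trained)
#' hyperparameter unless `alpha_trainable = TRUE`.
#'
#' @param n_filters number of multinomial kernels (>= 1).
#' @param filter_length kernel length L in bases (>= 1).
#' @param alpha positive softmax temperature.
#' @param alpha_trainable if `TRUE`, alpha is optimized together with the
#'   weights instead of being held fixed.
#' @param activation one of `"relu"`, `"sigmoid"`, `"tanh"`.
#' @param pooling one of `"max"`, `"sum"`, `"average"`; applied jointly over
#'   all windows of both strands, one pooled value per filter.
#' @param dropout_rate dropout fraction on the pooled features, in `[0, 1)`.
#' @param n_dense_layers 1 (linear head) or 2 (one hidden dense layer).
#' @param dense_hidden_units hidden width of the two-layer head (ReLU).
#' @param l2_factor non-negative L2 penalty on convolution and dense weights.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum training epochs (early stopping usually ends
#'   training sooner).
#' @param early_stopping_patience epochs without validation-MSE improvement
#'   before stopping; best weights are restored.
#' @param seed integer seed for weight initialization, shuffling and dropout.
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_filters = 512L,
                         filter_length = 12L,
                         alpha = 120,
                         alpha_trainable = FALSE,
                         activation = c("relu", "sigmoid", "tanh"),
                         pooling = c("max", "sum", "average"),
                         dropout_rate = 0.4,
                         n_dense_layers = 1L,
                         dense_hidden_units = 16L,
                         l2_factor = 0.001,
                         batch_size = 64L,
                         learning_rate = 0.001,
                         max_epochs = 100L,
                         early_stopping_patience = 10L,
                         seed = 1L) {
  activation <- match.arg(activation)
  pooling <- match.arg(pooling)
  if (!is_count(n_filters)) mc_stop("n_filters must be a count >= 1", "motifconv_config_error")
  if (!is_count(filter_length)) mc_stop("filter_length must be a count >= 1", "motifconv_config_error")
  if (!is_scalar_num(alpha) || alpha <= 0) mc_stop("alpha must be > 0", "motifconv_config_error")
  if (!is_scalar_num(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    mc_stop("dropout_rate must be in [0, 1)", "motifconv_config_error")
  }
  if (!n_dense_layers %in% c(1L, 2L)) mc_stop("n_dense_layers must be 1 or 2", "motifconv_config_error")
  if (!is_count(dense_hidden_units)) mc_stop("dense_hidden_units must be a count", "motifconv_config_error")
  if (!is_scalar_num(l2_factor) || l2_factor < 0) mc_stop("l2_factor must be >= 0", "motifconv_config_error")
  if (!is_count(batch_size)) mc_stop("batch_size must be a count", "motifconv_config_error")
  if (!is_scalar_num(learning_rate) || learning_rate <= 0) {
    mc_stop("learning_rate must be > 0", "motifconv_config_error")
  }
  if (!is_count(max_epochs, min = 0L)) mc_stop("max_epochs must be a count >= 0", "motifconv_config_error")
  if (!is_count(early_stopping_patience, min = 0L)) {
    mc_stop("early_stopping_patience must be a count >= 0", "motifconv_config_error")
  }
  structure(list(n_filters = as.integer(n_filters),
                 filter_length = as.integer(filter_length),
                 alpha = alpha, alpha_trainable = isTRUE(alpha_trainable),
                 activation = activation, pooling = pooling,
                 dropout_rate = dropout_rate,
                 n_dense_layers = as.integer(n_dense_layers),
                 dense_hidden_units = as.integer(dense_hidden_units),
                 l2_factor = l2_factor,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Conventional CNN baseline configuration
#'
#' Configuration of the unconstrained-convolution baseline: a stack of
#' standard convolution layers (default the searched optimum of five layers
#' with 512, 256, 64, 64 and 64 filters, all of length 5, ELU activation),
#' followed by the same joint-strand pooling, dropout and dense head as the
#' multinomial model. Default dropout 0.5 and batch size 32.
#'
#' @param conv_filters integer vector, filters per convolution layer.
#' @param conv_lengths integer vector (recycled), filter length per layer.
#' @param activation one of `"elu"`, `"relu"`, `"sigmoid"`, `"tanh"`.
#' @inheritParams model_config
#' @return an object of class `cnn_config`.
#' @export
conventional_cnn_config <- function(conv_filters = c(512L, 256L, 64L, 64L, 64L),
                                    conv_lengths = 5L,
                                    activation = c("elu", "relu", "sigmoid", "tanh"),
                                    pooling = c("max", "sum", "average"),
                                    dropout_rate = 0.5,
                                    n_dense_layers = 1L,
                                    dense_hidden_units = 16L,
                                    l2_factor = 0.001,
                                    batch_size = 32L,
                                    learning_rate = 0.001,
                                    max_epochs = 100L,
                                    early_stopping_patience = 10L,
                                    seed = 1L) {
  activation <- match.arg(activation)
  pooling <- match.arg(pooling)
  conv_filters <- as.integer(conv_filters)
  if (length(conv_filters) < 1L || any(conv_filters < 1L)) {
    mc_stop("conv_filters must be a non-empty vector of counts", "motifconv_config_error")
  }
  conv_lengths <- rep_len(as.integer(conv_lengths), length(conv_filters))
  if (any(conv_lengths < 1L)) mc_stop("conv_lengths must be >= 1", "motifconv_config_error")
  base <- model_config(n_filters = conv_filters[length(conv_filters)],
                       filter_length = conv_lengths[1L],
                       activation = "relu", pooling = pooling,
                       dropout_rate = dropout_rate,
                       n_dense_layers = n_dense_layers,
                       dense_hidden_units = dense_hidden_units,
                       l2_factor = l2_factor, batch_size = batch_size,
                       learning_rate = learning_rate, max_epochs = max_epochs,
                       early_stopping_patience = early_stopping_patience,
                       seed = seed)
  base$activation <- activation
  base$conv_filters <- conv_filters
  base$conv_lengths <- conv_lengths
  class(base) <- c("cnn_config", "model_config")
  base
}

#' Read a model configuration file
#'
#' Configuration files are JSON objects whose keys mirror the arguments of
#' [model_config()] (or, with `"model": "conventional_cnn"`, of
#' [conventional_cnn_config()]). Unknown keys are rejected.
#'
#' @param path path to a JSON config file.
#' @return a `model_config` or `cnn_config`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) mc_stop(sprintf("config file not found: %s", path), "motifconv_io_error")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- raw$model %||% "multinomial"
  raw$model <- NULL
  builder <- if (identical(kind, "conventional_cnn")) conventional_cnn_config else model_config
  known <- names(formals(builder))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    mc_stop(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")),
            "motifconv_config_error")
  }
  do.call(builder, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
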