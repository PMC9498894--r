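#' Save and load model checkpoints
#'
#' Checkpoints are JSON text files holding the configuration, the raw
#' (pre-softmax) convolution weights, the dense head, the background and
#' the training history. Kernels are re-derivable from the raw weights, so
#' nothing interpretable is lost in a round trip.
#'
#' @param model a `multinom_cnn` or `conventional_cnn`.
#' @param path output path (conventionally `.json`).
#' @return `save_checkpoint()` returns the path invisibly;
#'   `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("multinom_cnn", "conventional_cnn")))
  ser_param <- function(p) {
    if (is.array(p) || is.matrix(p)) list(dim = dim(p), data = as.vector(p))
    else list(dim = NULL, data = as.vector(p))
  }
  obj <- list(
    format = "motifconv_checkpoint",
    version = 1L,
    model_class = class(model)[1L],
    config = unclass_config(model$config),
    config_class = class(model$config)[1L],
    background = if (!is.null(model$background)) as.vector(model$background$probs) else NULL,
    params = lapply(model$params, ser_param),
    trained = model$trained,
    input_length = model$input_length,
    best_epoch = model$best_epoch,
    history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out[!vapply(out, is.null, TRUE)]
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    mc_stop(sprintf("checkpoint not found: %s", path), "motifconv_io_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "motifconv_checkpoint")) {
    mc_stop("not a motifconv checkpoint file", "motifconv_parse_error")
  }
  cfg <- obj$config
  builder_args <- cfg[setdiff(names(cfg), c("conv_filters", "conv_lengths"))]
  config <- if (identical(obj$config_class, "cnn_config")) {
    do.call(conventional_cnn_config,
            c(list(conv_filters = cfg$conv_filters, conv_lengths = cfg$conv_lengths),
              builder_args[setdiff(names(builder_args),
                                   c("n_filters", "filter_length", "alpha",
                                     "alpha_trainable"))]))
  } else {
    do.call(model_config, builder_args)
  }
  params <- lapply(obj$params, function(p) {
    if (is.null(p$dim) || length(p$dim) == 0L) as.numeric(p$data)
    else array(as.numeric(p$data), dim = as.integer(p$dim))
  })
  model <- structure(
    list(config = config,
         params = params,
         trained = isTRUE(obj$trained),
         input_length = if (is.null(obj$input_length)) NA_integer_ else
           as.integer(obj$input_length),
         best_epoch = obj$best_epoch,
         history = if (is.null(obj$history)) NULL else as.data.frame(obj$history)),
    class = obj$model_class)
  if (!is.null(obj$background)) {
    model$background <- background_distribution(obj$background)
  }
  model
}
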