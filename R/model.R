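#' Mean squared error
#'
#' `(1/n) * sum((y - y_hat)^2)`, the training loss.
#'
#' @param y,y_hat numeric vectors of equal length `n >= 1`.
#' @return a single number.
#' @export
mse_loss <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    mc_stop("y and y_hat must have the same length", "motifconv_dim_error")
  }
  if (length(y) < 1L) mc_stop("empty vectors", "motifconv_dim_error")
  mean((y - y_hat)^2)
}

#' Build an untrained multinomial-convolution network
#'
#' Constructs the sequence-activity regression model: one convolution layer
#' whose kernels are multinomial distributions (derived from free weights
#' via a temperature-alpha softmax at every forward pass, so gradients flow
#' through the softmax), scoring every window of both the forward and
#' reverse-complement strand by the background-corrected log-likelihood
#' ratio; an elementwise activation; one jointly-pooled value per filter
#' over all windows of both strands; dropout; and a fully connected head
#' yielding one real output. The convolution has no bias term, preserving
#' the likelihood-ratio interpretation of the scores.
#'
#' Weights are glorot-uniform initialized from `config$seed`.
#'
#' @param config a [model_config()].
#' @param background a [background_distribution()].
#' @return an object of class `multinom_cnn`.
#' @export
build_multinom_cnn <- function(config = model_config(),
                               background = background_distribution()) {
  if (!inherits(config, "model_config") || inherits(config, "cnn_config")) {
    mc_stop("'config' must be a model_config()", "motifconv_config_error")
  }
  background <- as_background(background)
  L <- config$filter_length
  nf <- config$n_filters
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  # Raw weights are initialized so that the softmax logits alpha * X start at
  # glorot-uniform scale: at alpha ~ 100-140 an unscaled glorot draw saturates
  # the softmax and, combined with ReLU and max pooling, zeroes every gradient.
  params <- c(
    list(X = array(glorot_uniform(L * 4L * nf, 4L * L, L * nf) / config$alpha,
                   dim = c(L, 4L, nf)),
         alpha = config$alpha),
    init_dense(nf, config))
  structure(list(config = config, background = background, params = params,
                 trained = FALSE, input_length = NA_integer_, history = NULL),
            class = "multinom_cnn")
}

#' Build an untrained conventional CNN baseline
#'
#' The unconstrained-convolution comparator: a stack of standard valid-mode
#' convolution layers (with biases, no multinomial constraint and no
#' background correction), each followed by the configured activation, then
#' the same joint-strand pooling, dropout and dense head as
#' [build_multinom_cnn()]. A single-layer configuration reduces to an
#' ordinary one-layer CNN regressor.
#'
#' @param config a [conventional_cnn_config()].
#' @return an object of class `conventional_cnn`.
#' @export
build_conventional_cnn <- function(config = conventional_cnn_config()) {
  if (!inherits(config, "cnn_config")) {
    mc_stop("'config' must be a conventional_cnn_config()", "motifconv_config_error")
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  nlayer <- length(config$conv_filters)
  convs <- vector("list", nlayer)
  in_ch <- 4L
  params <- list()
  for (l in seq_len(nlayer)) {
    Ll <- config$conv_lengths[l]
    Fl <- config$conv_filters[l]
    params[[paste0("convW", l)]] <-
      matrix(glorot_uniform(Ll * in_ch * Fl, Ll * in_ch, Ll * Fl), Ll * in_ch, Fl)
    params[[paste0("convb", l)]] <- numeric(Fl)
    in_ch <- Fl
  }
  params <- c(params, init_dense(in_ch, config))
  structure(list(config = config, params = params, trained = FALSE,
                 input_length = NA_integer_, history = NULL),
            class = "conventional_cnn")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# ---- forward passes --------------------------------------------------------

# multinomial model forward on a code matrix; returns yhat (+ cache when
# training or features are requested)
forward_mcnn <- function(model, codes, training = FALSE, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  L <- cfg$filter_length
  nf <- cfg$n_filters
  m <- nrow(codes)
  nw <- ncol(codes) - L + 1L
  kt <- kernel_tensors(p$X, p$alpha, log(model$background$probs))
  Z <- im2col_onehot(codes, L)
  S1 <- Z %*% kt$Wf
  S2 <- Z %*% kt$Wr
  A1 <- act_fun(S1, cfg$activation)
  A2 <- act_fun(S2, cfg$activation)
  pl <- pool_joint(A1, A2, m, nw, nf, cfg$pooling)
  D <- NULL
  Pd <- pl$P
  if (training && cfg$dropout_rate > 0) {
    D <- matrix((stats::runif(m * nf) >= cfg$dropout_rate) / (1 - cfg$dropout_rate), m, nf)
    Pd <- pl$P * D
  }
  dn <- dense_forward(p, Pd, cfg)
  out <- list(yhat = dn$yhat, P = pl$P)
  if (keep) {
    out$cache <- list(Z = Z, S1 = S1, S2 = S2, idx = pl$idx, D = D, Pd = Pd,
                      dense = dn, kt = kt, m = m, nw = nw)
  }
  out
}

backward_mcnn <- function(model, fwd, gy) {
  cfg <- model$config
  p <- model$params
  cc <- fwd$cache
  L <- cfg$filter_length
  nf <- cfg$n_filters
  dn <- dense_backward(p, cc$Pd, cc$dense, gy, cfg)
  grads <- dn$grads
  dP <- if (is.null(cc$D)) dn$dPd else dn$dPd * cc$D
  pb <- pool_joint_backward(dP, cc$idx, cc$m, cc$nw, nf, cfg$pooling)
  dS1 <- pb$d1 * act_grad(cc$S1, cfg$activation)
  dS2 <- pb$d2 * act_grad(cc$S2, cfg$activation)
  dWf <- crossprod(cc$Z, dS1) + crossprod(cc$Z, dS2)[rc_flat_perm(L), , drop = FALSE]
  G <- aperm(array(dWf, dim = c(4L, L, nf)), c(2L, 1L, 3L))  # d loss / d lnT
  Tp <- cc$kt$probs
  rs <- G[, 1L, , drop = FALSE] + G[, 2L, , drop = FALSE] +
        G[, 3L, , drop = FALSE] + G[, 4L, , drop = FALSE]
  rs <- array(rs, dim = c(L, nf))
  dX <- array(0, dim = dim(p$X))
  for (j in 1:4) dX[, j, ] <- p$alpha * (G[, j, ] - rs * Tp[, j, ])
  grads$X <- dX
  if (cfg$alpha_trainable) {
    # d lnT[i,j] / d alpha = X[i,j] - sum_k T[i,k] X[i,k]
    E <- array(0, dim = c(L, nf))
    for (j in 1:4) E <- E + Tp[, j, ] * p$X[, j, ]
    da <- 0
    for (j in 1:4) da <- da + sum(G[, j, ] * (p$X[, j, ] - E))
    grads$alpha <- da
  }
  grads
}

forward_ccnn <- function(model, codes, training = FALSE, keep = FALSE) {
  cfg <- model$config
  p <- model$params
  m <- nrow(codes)
  nlayer <- length(cfg$conv_filters)
  strands <- list(fwd = codes, rc = rc_codes(codes))
  caches <- list()
  tops <- list()
  for (s in names(strands)) {
    I <- onehot_array(strands[[s]])
    layer_cache <- vector("list", nlayer)
    for (l in seq_len(nlayer)) {
      Ll <- cfg$conv_lengths[l]
      C <- dim(I)[3L]
      len2 <- dim(I)[2L] - Ll + 1L
      if (len2 < 1L) mc_stop("sequence shorter than the convolution stack", "motifconv_dim_error")
      Z <- im2col_array(I, Ll)
      S <- sweep(Z %*% p[[paste0("convW", l)]], 2L, p[[paste0("convb", l)]], "+")
      A <- act_fun(S, cfg$activation)
      layer_cache[[l]] <- list(Z = Z, S = S, in_dim = dim(I))
      I <- aperm(array(A, dim = c(len2, m, ncol(A))), c(2L, 1L, 3L))
    }
    caches[[s]] <- layer_cache
    tops[[s]] <- I
  }
  nf <- dim(tops$fwd)[3L]
  nw <- dim(tops$fwd)[2L]
  A1 <- array(aperm(tops$fwd, c(2L, 1L, 3L)), dim = c(nw * m, nf))
  A2 <- array(aperm(tops$rc, c(2L, 1L, 3L)), dim = c(nw * m, nf))
  pl <- pool_joint(A1, A2, m, nw, nf, cfg$pooling)
  D <- NULL
  Pd <- pl$P
  if (training && cfg$dropout_rate > 0) {
    D <- matrix((stats::runif(m * nf) >= cfg$dropout_rate) / (1 - cfg$dropout_rate), m, nf)
    Pd <- pl$P * D
  }
  dn <- dense_forward(p, Pd, cfg)
  out <- list(yhat = dn$yhat, P = pl$P)
  if (keep) {
    out$cache <- list(caches = caches, idx = pl$idx, D = D, Pd = Pd, dense = dn,
                      m = m, nw = nw, nf = nf)
  }
  out
}

# im2col for a general n x len x C array
im2col_array <- function(I, L) {
  d <- dim(I)
  n <- d[1L]; len <- d[2L]; C <- d[3L]
  len2 <- len - L + 1L
  Z <- matrix(0, n * len2, L * C)
  for (i in seq_len(L)) {
    sl <- I[, i:(i + len2 - 1L), , drop = FALSE]           # n x len2 x C
    Z[, ((i - 1L) * C + 1L):(i * C)] <-
      array(aperm(sl, c(2L, 1L, 3L)), dim = c(len2 * n, C))
  }
  Z
}

col2im_array <- function(dZ, in_dim, L) {
  n <- in_dim[1L]; len <- in_dim[2L]; C <- in_dim[3L]
  len2 <- len - L + 1L
  dI <- array(0, dim = in_dim)
  for (i in seq_len(L)) {
    blk <- array(dZ[, ((i - 1L) * C + 1L):(i * C), drop = FALSE], dim = c(len2, n, C))
    dI[, i:(i + len2 - 1L), ] <- dI[, i:(i + len2 - 1L), , drop = FALSE] +
      aperm(blk, c(2L, 1L, 3L))
  }
  dI
}

backward_ccnn <- function(model, fwd, gy) {
  cfg <- model$config
  p <- model$params
  cc <- fwd$cache
  m <- cc$m; nw <- cc$nw; nf <- cc$nf
  nlayer <- length(cfg$conv_filters)
  dn <- dense_backward(p, cc$Pd, cc$dense, gy, cfg)
  grads <- dn$grads
  dP <- if (is.null(cc$D)) dn$dPd else dn$dPd * cc$D
  pb <- pool_joint_backward(dP, cc$idx, m, nw, nf, cfg$pooling)
  dtop <- list(fwd = pb$d1, rc = pb$d2)   # (m*nw) x nf, window-minor rows
  for (s in c("fwd", "rc")) {
    dA <- dtop[[s]]
    for (l in rev(seq_len(nlayer))) {
      lc <- cc$caches[[s]][[l]]
      dS <- dA * act_grad(lc$S, cfg$activation)
      wname <- paste0("convW", l); bname <- paste0("convb", l)
      gW <- crossprod(lc$Z, dS)
      gb <- colSums(dS)
      grads[[wname]] <- if (is.null(grads[[wname]])) gW else grads[[wname]] + gW
      grads[[bname]] <- if (is.null(grads[[bname]])) gb else grads[[bname]] + gb
      if (l > 1L) {
        dI <- col2im_array(dS %*% t(p[[wname]]), lc$in_dim, cfg$conv_lengths[l])
        len2 <- dim(dI)[2L]  # becomes the output length of layer l-1
        dA <- array(aperm(dI, c(2L, 1L, 3L)), dim = c(len2 * m, dim(dI)[3L]))
      }
    }
  }
  grads
}

model_forward <- function(model, codes, training = FALSE, keep = FALSE) {
  if (inherits(model, "multinom_cnn")) forward_mcnn(model, codes, training, keep)
  else forward_ccnn(model, codes, training, keep)
}

model_backward <- function(model, fwd, gy) {
  if (inherits(model, "multinom_cnn")) backward_mcnn(model, fwd, gy)
  else backward_ccnn(model, fwd, gy)
}

# parameter names carrying the L2 penalty (weights, not biases)
penalized_names <- function(model) {
  nm <- names(model$params)
  nm[grepl("^(X|convW|w$|W1|w2)", nm)]
}

l2_penalty <- function(model) {
  l2 <- model$config$l2_factor
  if (l2 == 0) return(0)
  l2 * sum(vapply(penalized_names(model), function(nm) sum(model$params[[nm]]^2), 0))
}

#' Train a sequence-activity model
#'
#' Minimizes mean squared error plus an L2 penalty on convolution and dense
#' weights with the Adam optimizer, in shuffled minibatches. When a
#' validation set is given, validation MSE is monitored after every epoch;
#' training stops after `early_stopping_patience` epochs without
#' improvement and the best weights are restored. All randomness
#' (shuffling, dropout) is seeded from `config$seed`.
#'
#' @param model an untrained (or previously trained) [build_multinom_cnn()]
#'   or [build_conventional_cnn()] model.
#' @param data training [mpra_dataset()].
#' @param validation optional validation `mpra_dataset` with the same
#'   sequence length; if `NULL`, training MSE is monitored instead.
#' @param config optional override of the model's configuration.
#' @return the model with updated weights, `trained = TRUE` and a
#'   `history` data frame (epoch, train_mse, monitor_mse).
#' @export
train_model <- function(model, data, validation = NULL, config = NULL) {
  stopifnot(inherits(model, c("multinom_cnn", "conventional_cnn")))
  if (!inherits(data, "mpra_dataset") || data$n < 1L) {
    mc_stop("training data must be a non-empty mpra_dataset", "motifconv_data_error")
  }
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  codes <- encode_codes(data$sequences)
  y <- data$activities
  val <- NULL
  if (!is.null(validation)) {
    stopifnot(inherits(validation, "mpra_dataset"))
    if (validation$seq_length != data$seq_length) {
      mc_stop("training and validation sequence lengths differ", "motifconv_dim_error")
    }
    val <- list(codes = encode_codes(validation$sequences), y = validation$activities)
  }
  model$input_length <- data$seq_length

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  opt <- adam_init(model$params)
  pen <- penalized_names(model)
  best <- list(params = model$params, monitor = Inf, epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = integer(), train_mse = numeric(), monitor_mse = numeric())
  n <- data$n
  nb <- max(1L, ceiling(n / cfg$batch_size))

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      rows <- ord[(((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n))]
      fwd <- model_forward(model, codes[rows, , drop = FALSE], training = TRUE, keep = TRUE)
      res <- fwd$yhat - y[rows]
      loss <- mean(res^2)
      if (!is.finite(loss)) {
        mc_stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
                "motifconv_divergence_error")
      }
      ep_loss <- ep_loss + loss * length(rows)
      grads <- model_backward(model, fwd, 2 * res / length(rows))
      if (cfg$l2_factor > 0) {
        for (nm in pen) grads[[nm]] <- grads[[nm]] + 2 * cfg$l2_factor * model$params[[nm]]
      }
      st <- adam_step(model$params, grads, opt, cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
    }
    train_mse <- ep_loss / n
    monitor <- if (is.null(val)) train_mse else {
      mse_loss(val$y, predict_codes(model, val$codes))
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_mse = train_mse,
                                   monitor_mse = monitor))
    if (monitor < best$monitor) {
      best <- list(params = model$params, monitor = monitor, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$early_stopping_patience && cfg$early_stopping_patience > 0L) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model$trained <- TRUE
  model
}

# batched deterministic forward pass on a code matrix
predict_codes <- function(model, codes, chunk = 512L) {
  n <- nrow(codes)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    out[rows] <- model_forward(model, codes[rows, , drop = FALSE])$yhat
  }
  out
}

#' Predict activities for new sequences
#'
#' Deterministic forward pass with dropout disabled. Sequences must have
#' the length the model was trained on (any length works for an untrained
#' model, provided it is at least the receptive-field length).
#'
#' @param object a `multinom_cnn` or `conventional_cnn` model.
#' @param sequences character vector of DNA strings, or an [mpra_dataset()].
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.multinom_cnn <- function(object, sequences, ...) {
  predict_model_impl(object, sequences)
}

#' @rdname predict.multinom_cnn
#' @export
predict.conventional_cnn <- function(object, sequences, ...) {
  predict_model_impl(object, sequences)
}

predict_model_impl <- function(model, sequences) {
  if (inherits(sequences, "mpra_dataset")) sequences <- sequences$sequences
  codes <- encode_codes(sequences)
  if (!is.na(model$input_length) && ncol(codes) != model$input_length) {
    mc_stop(sprintf("sequences have length %d but the model was trained on length %d",
                    ncol(codes), model$input_length), "motifconv_dim_error")
  }
  predict_codes(model, codes)
}

#' Pooled per-filter features
#'
#' Returns the matrix of pooled activated scores (one column per filter,
#' one row per sequence) that feeds the dense head — the interpretable
#' feature representation of the model.
#'
#' @inheritParams predict.multinom_cnn
#' @param model a built model.
#' @return numeric matrix, sequences x filters.
#' @export
pooled_features <- function(model, sequences) {
  if (inherits(sequences, "mpra_dataset")) sequences <- sequences$sequences
  codes <- encode_codes(sequences)
  model_forward(model, codes)$P
}

#' @export
print.multinom_cnn <- function(x, ...) {
  cat(sprintf("<multinom_cnn> %d multinomial kernels of length %d (alpha %g), %s%s\n",
              x$config$n_filters, x$config$filter_length, x$params$alpha,
              if (x$trained) "trained" else "untrained",
              if (x$trained) sprintf(" (best epoch %d)", x$best_epoch) else ""))
  invisible(x)
}

#' @export
print.conventional_cnn <- function(x, ...) {
  cat(sprintf("<conventional_cnn> %d conv layers (%s filters), %s\n",
              length(x$config$conv_filters),
              paste(x$config$conv_filters, collapse = "/"),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}
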