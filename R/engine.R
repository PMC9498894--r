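# Internal training engine: forward/backward passes and the Adam optimizer.
#
# There is no deep-learning framework in the dependency set, so the two
# architectures are implemented directly with im2col-style matrix products.
# Layout conventions used throughout:
#   * sequence codes: integer matrix n x N, 1..4 = A,C,G,T, 0 = N
#   * window matrices: rows ordered sequence-major, window-minor, i.e.
#     row (s-1)*Nw + w is window w of sequence s
#   * flattened kernels: column (i-1)*4 + j is position i, base j

# ---- one-hot expansion -----------------------------------------------------

# (n*Nw) x (4L) 0/1 matrix of all length-L windows of all sequences
im2col_onehot <- function(codes, L) {
  n <- nrow(codes)
  N <- ncol(codes)
  nw <- N - L + 1L
  if (nw < 1L) {
    mc_stop(sprintf("sequence length %d is shorter than kernel length %d", N, L),
            "motifconv_dim_error")
  }
  Z <- matrix(0, nrow = n * nw, ncol = 4L * L)
  for (i in seq_len(L)) {
    b <- as.vector(t(codes[, i:(i + nw - 1L), drop = FALSE]))  # window-minor order
    keep <- b > 0L
    if (any(keep)) Z[cbind(which(keep), (i - 1L) * 4L + b[keep])] <- 1
  }
  Z
}

# n x N x 4 one-hot array (conventional CNN input)
onehot_array <- function(codes) {
  n <- nrow(codes)
  N <- ncol(codes)
  arr <- array(0, dim = c(n, N, 4L))
  idx <- which(codes > 0L, arr.ind = TRUE)
  arr[cbind(idx[, 1L], idx[, 2L], codes[idx])] <- 1
  arr
}

# ---- activations -----------------------------------------------------------

act_fun <- function(x, kind) {
  switch(kind,
         relu = pmax(x, 0),
         elu = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
         sigmoid = 1 / (1 + exp(-x)),
         tanh = tanh(x),
         mc_stop(sprintf("unknown activation '%s'", kind), "motifconv_config_error"))
}

# derivative given pre-activation x
act_grad <- function(x, kind) {
  switch(kind,
         relu = (x > 0) * 1,
         elu = ifelse(x > 0, 1, exp(pmin(x, 0))),
         sigmoid = { s <- 1 / (1 + exp(-x)); s * (1 - s) },
         tanh = 1 - tanh(x)^2)
}

# ---- initialization --------------------------------------------------------

glorot_uniform <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

# ---- multinomial kernel algebra -------------------------------------------

# permutation of flattened-kernel columns implementing reverse complement
rc_flat_perm <- function(L) {
  i <- rep(seq_len(L), each = 4L)
  j <- rep(1:4, L)
  (L - i) * 4L + (5L - j)
}

# From the raw weight array X (L x 4 x F) compute, per filter, ln T via the
# stable log-softmax (alpha*X minus row log-sum-exp) and return the
# flattened log-likelihood-ratio kernels for both strands plus the
# probability array needed by the backward pass.
kernel_tensors <- function(X, alpha, log_bg) {
  d <- dim(X)
  L <- d[1L]; nf <- d[3L]
  Zm <- matrix(aperm(alpha * X, c(1L, 3L, 2L)), ncol = 4L)  # (L*nf) x 4, row = i + (f-1)L
  m <- pmax(Zm[, 1L], Zm[, 2L], Zm[, 3L], Zm[, 4L])
  e1 <- exp(Zm[, 1L] - m); e2 <- exp(Zm[, 2L] - m)
  e3 <- exp(Zm[, 3L] - m); e4 <- exp(Zm[, 4L] - m)
  lnT <- Zm - (m + log(e1 + e2 + e3 + e4))
  lnR <- sweep(lnT, 2L, log_bg, "-")
  arrR <- array(lnR, dim = c(L, nf, 4L))
  Wf <- matrix(aperm(arrR, c(3L, 1L, 2L)), nrow = 4L * L)   # (4L) x F
  probs <- aperm(array(exp(lnT), dim = c(L, nf, 4L)), c(1L, 3L, 2L))  # L x 4 x F
  list(Wf = Wf, Wr = Wf[rc_flat_perm(L), , drop = FALSE], probs = probs)
}

# ---- pooling ---------------------------------------------------------------

# A1, A2: (m*Nw) x F activated scores on the two strands; pools each filter
# jointly over all 2*Nw windows. Returns pooled m x F matrix plus, for max
# pooling, the flat argmax needed by the backward pass.
pool_joint <- function(A1, A2, m, nw, nf, pooling) {
  big <- array(0, dim = c(2L * nw, m, nf))
  big[seq_len(nw), , ] <- array(A1, dim = c(nw, m, nf))
  big[(nw + 1L):(2L * nw), , ] <- array(A2, dim = c(nw, m, nf))
  dim(big) <- c(2L * nw, m * nf)
  if (pooling == "max") {
    tm <- t(big)
    idx <- max.col(tm, ties.method = "first")
    pooled <- tm[cbind(seq_along(idx), idx)]
    list(P = matrix(pooled, m, nf), idx = idx)
  } else {
    s <- .colSums(big, 2L * nw, m * nf)
    if (pooling == "average") s <- s / (2 * nw)
    list(P = matrix(s, m, nf), idx = NULL)
  }
}

# scatter pooled gradients back onto the two strands
pool_joint_backward <- function(dP, idx, m, nw, nf, pooling) {
  if (pooling == "max") {
    G <- numeric(2L * nw * m * nf)
    G[idx + 2L * nw * (seq_len(m * nf) - 1L)] <- as.vector(dP)
    dim(G) <- c(2L * nw, m, nf)
    d1 <- G[seq_len(nw), , , drop = FALSE]
    d2 <- G[(nw + 1L):(2L * nw), , , drop = FALSE]
    dim(d1) <- c(nw * m, nf); dim(d2) <- c(nw * m, nf)
    list(d1 = d1, d2 = d2)
  } else {
    scale <- if (pooling == "average") 1 / (2 * nw) else 1
    d <- dP[rep(seq_len(m), each = nw), , drop = FALSE] * scale
    list(d1 = d, d2 = d)
  }
}

# ---- dense head ------------------------------------------------------------

dense_forward <- function(params, Pd, cfg) {
  if (cfg$n_dense_layers == 1L) {
    list(yhat = as.vector(Pd %*% params$w + params$b))
  } else {
    H0 <- sweep(Pd %*% params$W1, 2L, params$b1, "+")
    H <- pmax(H0, 0)
    list(yhat = as.vector(H %*% params$w2 + params$b2), H0 = H0, H = H)
  }
}

dense_backward <- function(params, Pd, dense_cache, gy, cfg) {
  if (cfg$n_dense_layers == 1L) {
    list(grads = list(w = as.vector(crossprod(Pd, gy)), b = sum(gy)),
         dPd = outer(gy, as.vector(params$w)))
  } else {
    dH <- outer(gy, as.vector(params$w2)) * (dense_cache$H0 > 0)
    list(grads = list(W1 = crossprod(Pd, dH), b1 = colSums(dH),
                      w2 = as.vector(crossprod(dense_cache$H, gy)), b2 = sum(gy)),
         dPd = dH %*% t(params$W1))
  }
}

init_dense <- function(nf, cfg) {
  if (cfg$n_dense_layers == 1L) {
    list(w = matrix(glorot_uniform(nf, nf, 1L), ncol = 1L), b = 0)
  } else {
    h <- cfg$dense_hidden_units
    list(W1 = matrix(glorot_uniform(nf * h, nf, h), nf, h), b1 = numeric(h),
         w2 = matrix(glorot_uniform(h, h, 1L), ncol = 1L), b2 = 0)
  }
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zero <- function(p) { p[] <- 0; p }
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
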