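#' Background nucleotide distribution
#'
#' Probability of each base A, C, G, T used to background-correct
#' log-likelihood-ratio scores and to compute information content. The
#' default is the human genomic composition
#' (A 0.295, C 0.205, G 0.205, T 0.295).
#'
#' @param probs numeric length-4 vector of positive probabilities in the
#'   order A, C, G, T; must sum to 1 within 1e-9.
#' @return an object of class `background_distribution`.
#' @export
background_distribution <- function(probs = c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)) {
  probs <- as.numeric(probs)
  if (length(probs) != 4L || any(!is.finite(probs)) || any(probs <= 0)) {
    mc_stop("background must be 4 finite positive probabilities (A,C,G,T)",
            "motifconv_input_error")
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    mc_stop("background probabilities must sum to 1 within 1e-9", "motifconv_input_error")
  }
  structure(list(probs = stats::setNames(probs, BASES)), class = "background_distribution")
}

as_background <- function(background) {
  if (inherits(background, "background_distribution")) return(background)
  background_distribution(background)
}

#' Unconstrained convolution weights
#'
#' The free L x 4 real matrix that the multinomial (temperature-softmax)
#' transform turns into a position weight matrix. Column order is A,C,G,T.
#'
#' @param weights L x 4 numeric matrix with finite entries.
#' @return an object of class `raw_convolution`.
#' @export
raw_convolution <- function(weights) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L || nrow(weights) < 1L || any(!is.finite(weights))) {
    mc_stop("weights must be a finite L x 4 matrix", "motifconv_numeric_error")
  }
  colnames(weights) <- BASES
  structure(list(weights = weights, length = nrow(weights)), class = "raw_convolution")
}

# Row-wise log-softmax of alpha * X with max subtraction; returns L x 4 of
# log-probabilities. This is the only path used to obtain ln T: taking
# log(softmax(...)) would underflow for the alpha ~ 100-140 regime.
log_multinomial <- function(weights, alpha) {
  z <- alpha * weights
  m <- apply(z, 1L, max)
  z <- z - m
  z - log(rowSums(exp(z)))
}

#' Multinomial (temperature-softmax) kernel transform
#'
#' Maps an unconstrained L x 4 weight matrix X to a row-stochastic kernel
#' T with `T[i, j] = exp(alpha * X[i, j]) / sum_j' exp(alpha * X[i, j'])`.
#' Every row of T is a multinomial distribution over A,C,G,T, so T is
#' directly interpretable as a sequence motif. `alpha` is the softmax
#' temperature; large values (around 100-140) sharpen the kernel.
#'
#' @param x a [raw_convolution()] (or bare L x 4 matrix).
#' @param alpha positive softmax temperature.
#' @return an object of class `multinomial_kernel` with fields `probs`
#'   (L x 4 row-stochastic), `log_probs` (ln T, computed stably),
#'   `alpha`, `length` and `source` (the raw weights).
#' @export
multinomial_transform <- function(x, alpha) {
  if (!inherits(x, "raw_convolution")) x <- raw_convolution(x)
  if (!is_scalar_num(alpha) || alpha <= 0) {
    mc_stop("'alpha' must be a positive finite scalar", "motifconv_input_error")
  }
  lp <- log_multinomial(x$weights, alpha)
  probs <- exp(lp)
  colnames(probs) <- BASES
  structure(list(probs = probs, log_probs = lp, alpha = alpha,
                 length = nrow(probs), source = x),
            class = "multinomial_kernel")
}

#' @export
print.multinomial_kernel <- function(x, ...) {
  cat(sprintf("<multinomial_kernel> length %d, alpha %g\n", x$length, x$alpha))
  print(round(x$probs, 4))
  invisible(x)
}

kernel_log_ratio <- function(kernel, background) {
  b <- as_background(background)
  sweep(kernel$log_probs, 2L, log(b$probs), "-")
}

#' Log-likelihood-ratio score of one window
#'
#' For a kernel T of length L, an L-base one-hot window s and a background
#' B, computes `sum_i sum_j ln(T[i,j] / B[j]) * s[i,j]` (natural log):
#' the log of the likelihood of generating s from T over the likelihood
#' of generating it from B. All-zero rows (ambiguous bases) contribute 0.
#'
#' @param kernel a [multinomial_transform()] result.
#' @param subseq an `onehot_sequence` whose length equals the kernel length.
#' @param background a [background_distribution()] (default human genomic).
#' @return a single numeric LLR in nats.
#' @export
llr_score <- function(kernel, subseq, background = background_distribution()) {
  stopifnot(inherits(kernel, "multinomial_kernel"), inherits(subseq, "onehot_sequence"))
  if (subseq$length != kernel$length) {
    mc_stop(sprintf("window length %d does not match kernel length %d",
                    subseq$length, kernel$length), "motifconv_dim_error")
  }
  sum(kernel_log_ratio(kernel, background) * subseq$matrix)
}

#' Scan a sequence with a multinomial kernel
#'
#' Slides the kernel over every length-L window of an N-base sequence
#' (valid windows only, no padding) and returns the N - L + 1
#' log-likelihood-ratio scores. Windows are half-open `[k, k + L)` with
#' 0-based start k, so element `k + 1` of the result scores the window
#' starting at 0-based position k.
#'
#' @inheritParams llr_score
#' @param seq an `onehot_sequence` of length N >= L.
#' @return numeric vector of length N - L + 1.
#' @export
scan_llr <- function(kernel, seq, background = background_distribution()) {
  stopifnot(inherits(kernel, "multinomial_kernel"), inherits(seq, "onehot_sequence"))
  L <- kernel$length
  n <- seq$length
  if (n < L) {
    mc_stop(sprintf("sequence length %d is shorter than kernel length %d", n, L),
            "motifconv_dim_error")
  }
  lr <- kernel_log_ratio(kernel, background)
  nw <- n - L + 1L
  s <- seq$matrix
  out <- numeric(nw)
  # contribution of kernel position i to every window at once
  for (i in seq_len(L)) {
    out <- out + as.vector(s[i:(i + nw - 1L), , drop = FALSE] %*% lr[i, ])
  }
  out
}

# reverse-complement a kernel: reverse positions, swap A<->T and C<->G
rc_kernel <- function(kernel) {
  w <- kernel$source$weights[rev(seq_len(kernel$length)), c(4L, 3L, 2L, 1L), drop = FALSE]
  multinomial_transform(raw_convolution(w), kernel$alpha)
}
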