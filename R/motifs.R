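#' Sequence motif (position weight matrix)
#'
#' An L x 4 row-stochastic matrix over A,C,G,T, optionally annotated with
#' the dense-layer weight of the filter it came from. The regulatory role
#' follows the weight sign: positive = activator, negative = repressor,
#' exactly zero (or absent) = unassigned.
#'
#' @param probs L x 4 matrix; every row must sum to 1 within 1e-6.
#' @param name motif label.
#' @param dense_weight optional real weight from the fully connected layer.
#' @return an object of class `motif`.
#' @export
motif <- function(probs, name = "motif", dense_weight = NULL) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L || nrow(probs) < 1L || any(!is.finite(probs)) || any(probs < 0)) {
    mc_stop("motif probabilities must be a finite non-negative L x 4 matrix",
            "motifconv_input_error")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    mc_stop("motif rows must sum to 1 within 1e-6", "motifconv_input_error")
  }
  colnames(probs) <- BASES
  role <- "unassigned"
  if (!is.null(dense_weight)) {
    stopifnot(is_scalar_num(dense_weight))
    if (dense_weight > 0) role <- "activator" else if (dense_weight < 0) role <- "repressor"
  }
  structure(list(probs = probs, name = as.character(name),
                 dense_weight = dense_weight, role = role,
                 length = nrow(probs)),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  w <- if (is.null(x$dense_weight)) "" else sprintf(", weight %.4g", x$dense_weight)
  cat(sprintf("<motif> %s: length %d, %s%s\n", x$name, x$length, x$role, w))
  invisible(x)
}

# reverse complement of a motif probability matrix
rc_motif_probs <- function(probs) {
  out <- probs[rev(seq_len(nrow(probs))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- BASES
  out
}

#' Extract multinomial motifs from a trained model
#'
#' Applies the temperature-alpha softmax to every raw convolution of the
#' model, yielding one position weight matrix per filter, and attaches the
#' paired fully-connected weight and the activator/repressor role derived
#' from its sign (single-dense-layer head only; with two dense layers the
#' per-filter role is not identifiable and motifs are unassigned).
#'
#' @param model a trained `multinom_cnn`.
#' @return list of [motif()] objects, one per filter.
#' @export
extract_motifs <- function(model) {
  stopifnot(inherits(model, "multinom_cnn"))
  nf <- model$config$n_filters
  single <- model$config$n_dense_layers == 1L
  lapply(seq_len(nf), function(f) {
    k <- multinomial_transform(raw_convolution(model$params$X[, , f]), model$params$alpha)
    motif(k$probs, name = sprintf("filter_%03d", f),
          dense_weight = if (single) as.vector(model$params$w)[f] else NULL)
  })
}

#' Information content per position (ICP)
#'
#' Rows are first renormalized by their sums, then the mean per-position
#' Kullback-Leibler divergence from the background is computed in bits:
#' `(1/L) * sum_i sum_j M[i,j] * log2(M[i,j] / B[j])`, with the convention
#' `0 * log2(0 / B) = 0`. ICP is non-negative and measures motif
#' specificity; a motif equal to the background scores 0.
#'
#' @param x a [motif()] (or bare L x 4 non-negative matrix).
#' @param background a [background_distribution()].
#' @return bits per position (single number).
#' @export
icp <- function(x, background = background_distribution()) {
  probs <- if (inherits(x, "motif")) x$probs else as.matrix(x)
  b <- as_background(background)$probs
  rs <- rowSums(probs)
  if (any(rs <= 0)) mc_stop("degenerate motif: a row sums to 0", "motifconv_input_error")
  m <- probs / rs
  term <- m * log2(sweep(m, 2L, b, "/"))
  term[m == 0] <- 0
  sum(term) / nrow(m)
}

# Welch two-sample t statistic, one-sided alternative mean(a) < mean(b).
# Implemented from the closed form (not delegated to stats::t.test) so the
# test suite can check it against R's reference implementation.
welch_less <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na
  vb <- stats::var(b) / nb
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = tstat, df = df, p = stats::pt(tstat, df))
}

#' Compare specificity of two motif sets
#'
#' Computes ICP for every motif in a reference set (for example a motif
#' database) and in a learned set, then performs a Welch unequal-variance
#' two-sample t-test of the one-sided hypothesis that the reference mean
#' ICP is less than the learned mean ICP. A small p-value therefore means
#' the learned motifs are at least as specific as the reference motifs.
#'
#' @param reference,learned lists of [motif()] objects, each of size >= 2.
#' @param background a [background_distribution()].
#' @return an `icp_report` with `icp_reference`, `icp_learned`,
#'   `t_statistic`, `df`, `p_value`, `alternative = "less"`.
#' @export
compare_icp <- function(reference, learned, background = background_distribution()) {
  if (!is.list(reference) || length(reference) < 2L ||
      !is.list(learned) || length(learned) < 2L) {
    mc_stop("both motif sets must contain at least 2 motifs", "motifconv_data_error")
  }
  a <- vapply(reference, icp, 0, background = background)
  b <- vapply(learned, icp, 0, background = background)
  w <- welch_less(a, b)
  structure(list(icp_reference = a, icp_learned = b,
                 t_statistic = w$t, df = w$df, p_value = w$p,
                 alternative = "less"),
            class = "icp_report")
}

#' @export
print.icp_report <- function(x, ...) {
  cat(sprintf(paste0("<icp_report> reference mean %.3f bits (n=%d), learned mean %.3f",
                     " bits (n=%d)\n  Welch t = %.4g, df = %.1f, one-sided p = %.4g",
                     " (alternative: reference < learned)\n"),
              mean(x$icp_reference), length(x$icp_reference),
              mean(x$icp_learned), length(x$icp_learned),
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Write an ICP/role table for extracted motifs
#'
#' Tab-delimited text with one row per motif: name, ICP (bits/position),
#' dense weight and role.
#'
#' @param motifs list of [motif()] objects.
#' @param path output path.
#' @param background a [background_distribution()].
#' @export
write_motif_report <- function(motifs, path, background = background_distribution()) {
  df <- data.frame(
    name = vapply(motifs, `[[`, "", "name"),
    icp = vapply(motifs, icp, 0, background = background),
    dense_weight = vapply(motifs, function(m) m$dense_weight %||% NA_real_, 0),
    role = vapply(motifs, `[[`, "", "role"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
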