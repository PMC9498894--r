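#' One-hot encode a DNA sequence
#'
#' Converts a DNA string over the alphabet A, C, G, T (plus the ambiguity
#' code N) into an N x 4 indicator matrix with the fixed column order
#' A, C, G, T. Row i is the indicator vector of base i; ambiguous bases (N)
#' become all-zero rows, so that they contribute nothing to any
#' log-likelihood-ratio term.
#'
#' @param sequence a single DNA string, case-insensitive.
#' @return an object of class `onehot_sequence`: a list with `matrix`
#'   (N x 4, 0/1, columns A,C,G,T), `length` (N) and `strand`
#'   (`"forward"` or `"reverse_complement"`).
#' @examples
#' one_hot_encode("ACGT")$matrix
#' @export
one_hot_encode <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L) {
    mc_stop("'sequence' must be a single non-empty string", "motifconv_input_error")
  }
  codes <- encode_codes(sequence)[1L, ]
  n <- length(codes)
  m <- matrix(0, nrow = n, ncol = 4L, dimnames = list(NULL, BASES))
  nz <- codes != 0L
  m[cbind(which(nz), codes[nz])] <- 1
  new_onehot(m, "forward")
}

new_onehot <- function(m, strand) {
  structure(list(matrix = m, length = nrow(m), strand = strand),
            class = "onehot_sequence")
}

#' Reverse complement of a one-hot encoded sequence
#'
#' Reverses the rows and swaps the columns A<->T and C<->G. Applying the
#' operation twice restores the input; the `strand` field is flipped.
#'
#' @param encoded an [one_hot_encode()] result.
#' @return an `onehot_sequence` on the opposite strand.
#' @export
reverse_complement <- function(encoded) {
  stopifnot(inherits(encoded, "onehot_sequence"))
  m <- encoded$matrix[rev(seq_len(encoded$length)), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(m) <- BASES
  new_onehot(m, if (identical(encoded$strand, "forward")) "reverse_complement" else "forward")
}

#' @export
print.onehot_sequence <- function(x, ...) {
  cat(sprintf("<onehot_sequence> %d bases, %s strand\n", x$length, x$strand))
  invisible(x)
}
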