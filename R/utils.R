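# internal helpers shared across the package

BASES <- c("A", "C", "G", "T")

mc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "motifconv_error")))
}

#' @noRd
is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Encode sequences as an integer matrix, 1..4 = A,C,G,T and 0 = N.
# All sequences must share one length.
encode_codes <- function(sequences) {
  sequences <- toupper(sequences)
  n <- length(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    mc_stop("all sequences must have the same length", "motifconv_dim_error")
  }
  chars <- strsplit(sequences, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  code <- match(flat, BASES)
  bad <- is.na(code) & flat != "N"
  if (any(bad)) {
    k <- which(bad)[1L]
    pos <- ((k - 1L) %% lens[1L]) + 1L
    seq_i <- ((k - 1L) %/% lens[1L]) + 1L
    mc_stop(sprintf("invalid character '%s' at position %d of sequence %d (alphabet is A,C,G,T,N)",
                    flat[k], pos, seq_i), "motifconv_alphabet_error")
  }
  code[is.na(code)] <- 0L
  matrix(code, nrow = n, ncol = lens[1L], byrow = TRUE)
}

# reverse-complement of an integer code matrix (0 = N stays 0)
rc_codes <- function(codes) {
  out <- codes[, rev(seq_len(ncol(codes))), drop = FALSE]
  nz <- out != 0L
  out[nz] <- 5L - out[nz]
  out
}

codes_to_strings <- function(codes) {
  apply(codes, 1L, function(v) paste(ifelse(v == 0L, "N", BASES[pmax(v, 1L)]), collapse = ""))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
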