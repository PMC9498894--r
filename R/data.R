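#' MPRA-style sequence-activity dataset
#'
#' Pairs equal-length DNA sequences with one real-valued activity each,
#' the unit of data for massively-parallel-reporter-assay style regression.
#'
#' @param sequences character vector of equal-length DNA strings (A,C,G,T,N).
#' @param activities numeric vector, one activity per sequence.
#' @param ids optional labels; defaults to `seq_1 ... seq_n`.
#' @return an object of class `mpra_dataset` with fields `sequences`,
#'   `activities`, `ids`, `n` and `seq_length`.
#' @export
mpra_dataset <- function(sequences, activities, ids = NULL) {
  sequences <- toupper(as.character(sequences))
  activities <- as.numeric(activities)
  if (length(sequences) < 1L) mc_stop("dataset is empty", "motifconv_data_error")
  if (length(sequences) != length(activities)) {
    mc_stop("sequence and activity counts differ", "motifconv_dim_error")
  }
  if (any(!is.finite(activities))) {
    mc_stop("activities must be finite", "motifconv_data_error")
  }
  codes <- encode_codes(sequences)  # validates alphabet and equal lengths
  if (is.null(ids)) ids <- paste0("seq_", seq_along(sequences))
  ids <- as.character(ids)
  if (length(ids) != length(sequences) || anyDuplicated(ids)) {
    mc_stop("ids must be unique and match the number of sequences", "motifconv_data_error")
  }
  structure(list(sequences = sequences, activities = activities, ids = ids,
                 n = length(sequences), seq_length = ncol(codes)),
            class = "mpra_dataset")
}

#' @export
print.mpra_dataset <- function(x, ...) {
  cat(sprintf("<mpra_dataset> %d sequences of length %d; activity range [%.3g, %.3g]\n",
              x$n, x$seq_length, min(x$activities), max(x$activities)))
  invisible(x)
}

subset_dataset <- function(data, ids) {
  idx <- match(ids, data$ids)
  if (anyNA(idx)) mc_stop("unknown ids in subset", "motifconv_data_error")
  mpra_dataset(data$sequences[idx], data$activities[idx], data$ids[idx])
}

#' Read and write activity tables
#'
#' The on-disk format is tab-delimited text with a header and the columns
#' `id`, `sequence`, `activity`. The reader validates the alphabet and that
#' all sequences share one length.
#'
#' @param path file path.
#' @return `read_activity_table()` returns an [mpra_dataset()].
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) {
    mc_stop(sprintf("activity table not found: %s", path), "motifconv_io_error")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "sequence", "activity")
  if (!all(need %in% names(df))) {
    mc_stop("activity table needs columns id, sequence, activity", "motifconv_io_error")
  }
  mpra_dataset(df$sequence, df$activity, df$id)
}

#' @rdname read_activity_table
#' @param data an [mpra_dataset()].
#' @export
write_activity_table <- function(data, path) {
  stopifnot(inherits(data, "mpra_dataset"))
  df <- data.frame(id = data$ids, sequence = data$sequences,
                   activity = data$activities, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers around Biostrings; sequences are uppercased on read.
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    mc_stop(sprintf("FASTA file not found: %s", path), "motifconv_io_error")
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector of DNA strings.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(x))) names(x) <- paste0("seq_", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
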