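#' Write motifs in MEME minimal text format
#'
#' Produces a MEME minimal (version 4) motif file: version line, `ALPHABET=
#' ACGT`, `strands: + -`, a background-frequency line carrying the model
#' background, and one `letter-probability matrix` block per motif with
#' `w = L` and probabilities printed to six decimals. The format is the
#' lingua franca of motif tools (Tomtom, FIMO, ...), so exported kernels
#' can be searched against databases such as HOCOMOCO externally.
#'
#' @param motifs non-empty list of [motif()] objects.
#' @param path output file path.
#' @param background a [background_distribution()] written to the
#'   background line.
#' @return the path, invisibly.
#' @export
write_meme <- function(motifs, path, background = background_distribution()) {
  if (!is.list(motifs) || length(motifs) < 1L ||
      !all(vapply(motifs, inherits, TRUE, "motif"))) {
    mc_stop("motifs must be a non-empty list of motif objects", "motifconv_input_error")
  }
  b <- as_background(background)$probs
  con <- tryCatch(file(path, "w"), error = function(e) {
    mc_stop(sprintf("cannot open '%s' for writing", path), "motifconv_io_error")
  })
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f", b[1], b[2], b[3], b[4]),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       m$length), con)
    writeLines(apply(m$probs, 1L, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                      r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a MEME minimal motif file
#'
#' Parses MEME minimal text format into a list of [motif()] objects. Rows
#' whose sums deviate from 1 by at most 1e-3 (printing round-off) are
#' renormalized; larger deviations are a parse error reporting the line
#' number. Dense weights are not part of the format, so roles come back
#' unassigned.
#'
#' @param path path to a MEME minimal format file.
#' @return list of [motif()] objects with names preserved.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) mc_stop(sprintf("MEME file not found: %s", path), "motifconv_io_error")
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines))) {
    mc_stop("not a MEME minimal file: missing 'MEME version' line", "motifconv_parse_error")
  }
  motifs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "MOTIF")) {
      name <- strsplit(ln, "\\s+")[[1]][2]
      if (is.na(name)) {
        mc_stop(sprintf("line %d: MOTIF line without a name", i), "motifconv_parse_error")
      }
      # find the letter-probability header
      j <- i + 1L
      while (j <= n && !grepl("^letter-probability matrix", trimws(lines[j]))) {
        if (startsWith(trimws(lines[j]), "MOTIF")) {
          mc_stop(sprintf("line %d: MOTIF block without a letter-probability matrix", i),
                  "motifconv_parse_error")
        }
        j <- j + 1L
      }
      if (j > n) {
        mc_stop(sprintf("line %d: MOTIF block without a letter-probability matrix", i),
                "motifconv_parse_error")
      }
      w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", trimws(lines[j]))))
      rows <- list()
      j <- j + 1L
      while (j <= n) {
        row_ln <- trimws(lines[j])
        if (row_ln == "" || startsWith(row_ln, "MOTIF") || grepl("^URL", row_ln)) break
        vals <- suppressWarnings(as.numeric(strsplit(row_ln, "\\s+")[[1]]))
        if (length(vals) != 4L || anyNA(vals)) {
          mc_stop(sprintf("line %d: expected 4 numeric probabilities", j),
                  "motifconv_parse_error")
        }
        if (abs(sum(vals) - 1) > 1e-3) {
          mc_stop(sprintf("line %d: probabilities sum to %.4f (tolerance 1e-3)",
                          j, sum(vals)), "motifconv_parse_error")
        }
        rows[[length(rows) + 1L]] <- vals / sum(vals)
        j <- j + 1L
      }
      if (length(rows) == 0L) {
        mc_stop(sprintf("line %d: empty letter-probability matrix", i),
                "motifconv_parse_error")
      }
      if (!is.na(w) && w != length(rows)) {
        mc_stop(sprintf("line %d: header says w= %d but %d rows follow", i, w,
                        length(rows)), "motifconv_parse_error")
      }
      motifs[[length(motifs) + 1L]] <- motif(do.call(rbind, rows), name = name)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(motifs) == 0L) {
    mc_stop("no MOTIF blocks found", "motifconv_parse_error")
  }
  motifs
}
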