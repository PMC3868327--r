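# Multiple sequence alignment container and FASTA/Clustal input.

is_gap <- function(ch) ch %in% c("-", ".")

#' Construct an alignment map from aligned sequences
#'
#' @param sequences Named character vector of equal-length aligned rows
#'   (gaps as `-` or `.`).
#' @return Object of class `alignment_map`: list with `sequences`,
#'   `column_to_position` (per row: alignment column -> ungapped 1-based
#'   position, NA at gaps), `position_to_column` (the inverse),
#'   `conservation` (per column: "strict", "conservative" or "variable").
#' @export
alignment_map <- function(sequences) {
  if (length(sequences) < 2) stop("need at least 2 sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be named")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1) {
    off <- names(sequences)[lens != lens[[1]]][1]
    stop("ragged alignment: sequence '", off, "' has length ",
         nchar(sequences[off]), ", expected ", lens[[1]])
  }
  chars <- lapply(sequences, function(s) strsplit(s, "")[[1]])
  ncol_aln <- lens[[1]]
  column_to_position <- lapply(chars, function(ch) {
    pos <- cumsum(!is_gap(ch))
    pos[is_gap(ch)] <- NA_integer_
    as.integer(pos)
  })
  position_to_column <- lapply(column_to_position, function(c2p) {
    cols <- which(!is.na(c2p))
    out <- integer(0)
    out[c2p[cols]] <- cols
    out
  })
  mat <- do.call(rbind, chars)
  conservation <- apply(mat, 2, function(col) {
    if (any(is_gap(col))) return("variable")
    u <- unique(col)
    if (length(u) == 1) return("strict")
    in_group <- vapply(SUBSTITUTION_GROUPS,
                       function(g) all(u %in% g), logical(1))
    if (any(in_group)) "conservative" else "variable"
  })
  structure(list(sequences = sequences,
                 column_to_position = column_to_position,
                 position_to_column = position_to_column,
                 conservation = unname(conservation)),
            class = "alignment_map")
}

alignment_chars <- function(aln, row) strsplit(aln$sequences[[row]], "")[[1]]

#' Degap one alignment row back to its input sequence
#' @param aln An [alignment_map()].
#' @param row Sequence name.
#' @return Ungapped sequence string.
#' @export
degap <- function(aln, row) {
  ch <- alignment_chars(aln, row)
  paste(ch[!is_gap(ch)], collapse = "")
}

#' Read a multiple sequence alignment (FASTA or Clustal)
#'
#' The format is sniffed from the file content: a leading `>` means FASTA,
#' a `CLUSTAL` header means Clustal. All rows must have equal aligned
#' length.
#'
#' @param path Path to the alignment file.
#' @return An [alignment_map()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  seqs <- if (startsWith(first, ">")) {
    ss <- Biostrings::readAAStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    out
  } else if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    as.character(Biostrings::unmasked(
      Biostrings::readAAMultipleAlignment(path, format = "clustal")))
  } else {
    stop("unrecognised alignment format (expected FASTA or Clustal): ",
         path)
  }
  alignment_map(seqs)
}

#' Write an alignment map as aligned FASTA
#' @param aln An [alignment_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aln$sequences),
                              path, width = 60)
  invisible(path)
}

#' @export
print.alignment_map <- function(x, ...) {
  tb <- table(factor(x$conservation,
                     levels = c("strict", "conservative", "variable")))
  cat("alignment_map:", length(x$sequences), "sequences x",
      nchar(x$sequences[[1]]), "columns (",
      tb[["strict"]], "strict,", tb[["conservative"]], "conservative,",
      tb[["variable"]], "variable )\n")
  invisible(x)
}
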