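#' Multiple sequence alignment container
#'
#' An `msa` object stores an alignment as equal-length rows over the
#' 22-letter internal alphabet (20 amino acids, `-` gap, `X` unknown).
#' Row 1 is the query/target sequence and defines column numbering
#' (1-based).  The integer encoding of the alignment is kept alongside
#' the character rows so that downstream statistics never re-parse
#' strings.
#'
#' @param sequences character vector of aligned rows (equal lengths).
#' @param identifier free-text identifier for the family.
#' @return An object of class `msa` with fields `sequences`, `mat`
#'   (N x L integer matrix), `N`, `L`, `query_index`, `identifier`.
#' @export
msa <- function(sequences, identifier = "") {
  if (length(sequences) < 1L) stop("alignment must contain at least one sequence")
  lens <- nchar(sequences)
  if (any(lens != lens[1L])) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("ragged alignment: row %d has length %d, expected %d",
                 bad, lens[bad], lens[1L]))
  }
  if (lens[1L] < 1L) stop("alignment rows must have length >= 1")
  mat <- matrix(0L, nrow = length(sequences), ncol = lens[1L])
  for (r in seq_along(sequences)) mat[r, ] <- encode_sequence(sequences[r])
  canon <- vapply(seq_len(nrow(mat)), function(r) decode_codes(mat[r, ]), "")
  structure(
    list(sequences = canon, mat = mat, N = nrow(mat), L = ncol(mat),
         query_index = 1L, identifier = identifier),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa '%s': N = %d sequences, L = %d columns\n",
              x$identifier, x$N, x$L))
  invisible(x)
}

#' Read an alignment in PSICOV flat format
#'
#' One aligned sequence per line, no headers.  The first line is the
#' query.  Unknown characters are mapped to `X`.
#'
#' @param path file path.
#' @return an [msa] object.
#' @export
read_psicov <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty alignment file: %s", path))
  msa(trimws(lines), identifier = basename(path))
}

#' Write an alignment in PSICOV flat format
#' @param aln an [msa] object.
#' @param path output file path.
#' @export
write_psicov <- function(aln, path) {
  writeLines(aln$sequences, path)
  invisible(path)
}

.read_fasta_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop(sprintf("no FASTA records in %s", path))
  ends <- c(hdr[-1L] - 1L, length(lines))
  names <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(seq_along(hdr), function(k) {
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    paste(gsub("\\s", "", body), collapse = "")
  }, "")
  list(names = names, seqs = seqs)
}

#' Read an A3M alignment
#'
#' FASTA-like records where lowercase letters mark insertions relative
#' to the query (master) sequence; these columns are removed so that all
#' rows align to the query length.
#'
#' @param path file path.
#' @return an [msa] object.
#' @export
read_a3m <- function(path) {
  rec <- .read_fasta_records(path)
  stripped <- vapply(rec$seqs, function(s) {
    gsub("[a-z.]", "", s)
  }, "", USE.NAMES = FALSE)
  L <- nchar(stripped[1L])
  bad <- which(nchar(stripped) != L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "A3M record %d ('%s') has length %d after removing insertions; master length is %d",
      bad[1L], rec$names[bad[1L]], nchar(stripped[bad[1L]]), L))
  }
  msa(stripped, identifier = rec$names[1L])
}

#' Write an alignment in A3M format
#'
#' Canonical alignments carry no insertions, so the output is plain
#' aligned FASTA (a valid A3M file).
#'
#' @param aln an [msa] object.
#' @param path output file path.
#' @export
write_a3m <- function(aln, path) {
  ids <- if (nzchar(aln$identifier)) aln$identifier else "query"
  hdr <- c(ids, sprintf("seq%d", seq_len(aln$N - 1L) + 1L))
  out <- character(2L * aln$N)
  out[c(TRUE, FALSE)] <- paste0(">", hdr[seq_len(aln$N)])
  out[c(FALSE, TRUE)] <- aln$sequences
  writeLines(out, path)
  invisible(path)
}

#' Read an aligned FASTA alignment
#' @param path file path.
#' @return an [msa] object.
#' @export
read_fasta <- function(path) {
  rec <- .read_fasta_records(path)
  lens <- nchar(rec$seqs)
  if (any(lens != lens[1L])) {
    bad <- which(lens != lens[1L])[1L]
    stop(sprintf("aligned FASTA record %d ('%s') has length %d, expected %d",
                 bad, rec$names[bad], lens[bad], lens[1L]))
  }
  msa(rec$seqs, identifier = rec$names[1L])
}
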