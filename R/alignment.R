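# Alignments are stored as a character matrix: rows = sequences (rownames are
# identifiers), columns = alignment positions. Gap characters: '-' and '.'.

GAP_CHARS <- c("-", ".")

#' Build an alignment object from residue strings
#'
#' @param seqs Named character vector of equal-length residue strings.
#' @return A character matrix of class `aln` (rows sequences, columns sites).
#' @export
alignment <- function(seqs) {
  if (length(seqs) == 0L) abort("empty alignment")
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    abort("alignment sequences must be named")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- names(seqs)[lens != lens[1L]][1L]
    abort(sprintf("ragged alignment: row '%s' has length %d, expected %d",
                  bad, nchar(seqs[[bad]]), lens[1L]))
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = FALSE))
  rownames(m) <- names(seqs)
  class(m) <- c("aln", class(m))
  m
}

#' Read a protein alignment from FASTA or NEXUS
#'
#' FASTA is parsed directly; NEXUS character matrices (including interleaved
#' blocks) are read with `ape::read.nexus.data`.
#'
#' @param path Input file.
#' @param format `"fasta"`, `"nexus"`, or `"auto"` (by file content).
#' @return An `aln` matrix; gap characters `-` and `.` are preserved.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus" else
      if (startsWith(first, ">")) "fasta" else
        abort(sprintf("cannot determine alignment format of '%s'", path))
  }
  if (format == "fasta") {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    if (!length(hdr)) abort(sprintf("no FASTA records in '%s'", path))
    ids <- sub("^>\\s*", "", lines[hdr])
    ids <- sub("\\s.*$", "", ids)
    from <- hdr + 1L
    to <- c(hdr[-1L] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      if (from[i] > to[i]) "" else paste(lines[from[i]:to[i]], collapse = "")
    }, character(1))
    seqs <- gsub("\\s", "", seqs)
    names(seqs) <- ids
  } else {
    mat <- ape::read.nexus.data(path)
    seqs <- vapply(mat, paste, character(1), collapse = "")
    names(seqs) <- names(mat)
  }
  alignment(seqs)
}

#' Write an alignment to FASTA
#' @param a An `aln` matrix.
#' @param path Output file.
#' @export
write_alignment <- function(a, path) {
  seqs <- apply(unclass(a), 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(a), "\n", seqs), path)
  invisible(path)
}

#' Per-column occupancy of an alignment
#'
#' Occupancy is the fraction of rows whose character is not a gap (`-` or
#' `.`); ambiguity codes such as `X` count as occupied.
#'
#' @param a An `aln` matrix.
#' @return Numeric vector in `[0, 1]`, one value per column.
#' @export
column_occupancy <- function(a) {
  colMeans(!matrix(unclass(a) %in% GAP_CHARS, nrow = nrow(a)))
}

#' Occupancy-based alignment trimming
#'
#' Retains exactly the columns whose non-gap fraction is at least
#' `threshold`, in their original order (the gap-threshold semantics of
#' alignment curation tools, boundary inclusive). Idempotent.
#'
#' @param a An `aln` matrix.
#' @param threshold Minimum occupancy in `(0, 1]`; default 0.7.
#' @return The trimmed `aln`.
#' @export
occupancy_trim <- function(a, threshold = 0.7) {
  if (!inherits(a, "aln")) a <- alignment(a)
  if (nrow(a) == 0L || ncol(a) == 0L) abort("empty alignment")
  if (!(threshold > 0 && threshold <= 1)) abort("`threshold` must be in (0, 1]")
  keep <- column_occupancy(a) >= threshold
  out <- unclass(a)[, keep, drop = FALSE]
  class(out) <- c("aln", class(out))
  out
}

#' Consensus columns of an alignment
#'
#' Columns whose occupancy meets the threshold; used as the coordinate system
#' for exon-junction tabulation.
#'
#' @inheritParams occupancy_trim
#' @return Integer vector of consensus column indices (1-based).
#' @export
consensus_columns <- function(a, threshold = 0.7) {
  which(column_occupancy(a) >= threshold)
}
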