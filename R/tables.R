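# Tabular inputs: gene annotations (gene order on scaffolds) and all-vs-all
# similarity hits (BLAST outfmt-6 dialect). Both come back as tibbles.

#' Read a gene annotation table
#'
#' Accepts either a GFF3 file (only `gene` features are used; attribute `ID`
#' is the gene id) or a 5-column TSV `gene_id, scaffold, start, end, strand`
#' with a header. Coordinates are 1-based inclusive. Per-scaffold ordinal
#' indices (0-based) are assigned by start coordinate, ties broken by gene id.
#'
#' @param path Input file; `.gff`/`.gff3` triggers GFF parsing.
#' @return Tibble with columns `gene_id, scaffold, start, end, strand, ordinal`.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineno <- which(keep)
    bad <- which(lengths(rows) != 9L)
    if (length(bad)) {
      abort(sprintf("malformed GFF row at line %d (%d fields, expected 9)",
                    lineno[bad[1L]], length(rows[[bad[1L]]])))
    }
    m <- do.call(rbind, rows)
    gene <- m[, 3L] == "gene"
    ids <- sub("^.*ID=([^;]+).*$", "\\1", m[gene, 9L])
    ann <- tibble::tibble(
      gene_id = ids,
      scaffold = m[gene, 1L],
      start = suppressWarnings(as.integer(m[gene, 4L])),
      end = suppressWarnings(as.integer(m[gene, 5L])),
      strand = m[gene, 7L]
    )
  } else {
    ann <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             gene_id = "c", scaffold = "c",
                             start = "i", end = "i", strand = "c"))
  }
  annotation_table(ann)
}

#' Validate an annotation tibble and assign scaffold ordinals
#'
#' @param ann Tibble/data frame with `gene_id, scaffold, start, end, strand`.
#' @return The validated tibble with an `ordinal` column (0-based, per
#'   scaffold, ordered by start then gene id).
#' @export
annotation_table <- function(ann) {
  ann <- tibble::as_tibble(ann)
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  miss <- setdiff(need, names(ann))
  if (length(miss)) abort(paste0("annotation lacks column(s): ", paste(miss, collapse = ", ")))
  if (any(is.na(ann$start)) || any(is.na(ann$end))) {
    abort(sprintf("malformed annotation row %d: non-numeric coordinates",
                  which(is.na(ann$start) | is.na(ann$end))[1L]))
  }
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup)) abort(paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")))
  if (any(ann$start > ann$end)) {
    abort(sprintf("annotation row for '%s' has start > end",
                  ann$gene_id[which(ann$start > ann$end)[1L]]))
  }
  ann |>
    arrange(.data$scaffold, .data$start, .data$gene_id) |>
    group_by(.data$scaffold) |>
    mutate(ordinal = dplyr::row_number() - 1L) |>
    ungroup()
}

#' Read an all-vs-all similarity hit table
#'
#' Parses BLAST outfmt-6-compatible TSV. Two layouts are accepted: the
#' standard 12 columns plus a sidecar length table, or 14 columns with
#' `qlen`/`slen` appended. Coverage of the longer sequence is computed as
#' `alignment length / max(qlen, slen)` when not supplied.
#'
#' @param path Hits TSV (no header, outfmt-6 column order).
#' @param lengths Optional tibble `id, length` (required for the 12-column
#'   layout).
#' @return Tibble with columns `query, subject, pident, length, evalue,
#'   qlen, slen, coverage`.
#' @export
read_hits <- function(path, lengths = NULL) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 12L) abort("hit table must have at least 12 outfmt-6 columns")
  hits <- tibble::tibble(
    query = as.character(raw[[1L]]),
    subject = as.character(raw[[2L]]),
    pident = as.numeric(raw[[3L]]),
    length = as.integer(raw[[4L]]),
    evalue = as.numeric(raw[[11L]])
  )
  if (ncol(raw) >= 14L) {
    hits$qlen <- as.integer(raw[[13L]])
    hits$slen <- as.integer(raw[[14L]])
  } else {
    if (is.null(lengths)) {
      abort("12-column hit table needs a `lengths` sidecar (id, length)")
    }
    lengths <- tibble::as_tibble(lengths)
    lk <- stats::setNames(lengths$length, lengths$id)
    missing <- setdiff(unique(c(hits$query, hits$subject)), names(lk))
    if (length(missing)) {
      abort(paste0("no sequence length for id(s): ", paste(missing, collapse = ", ")))
    }
    hits$qlen <- as.integer(lk[hits$query])
    hits$slen <- as.integer(lk[hits$subject])
  }
  hit_table(hits)
}

#' Validate a hit tibble and derive coverage
#'
#' @param hits Tibble with `query, subject, length, evalue, qlen, slen` (and
#'   optionally `coverage`).
#' @return The validated tibble with `coverage` in `[0, 1]`.
#' @export
hit_table <- function(hits) {
  hits <- tibble::as_tibble(hits)
  if (any(hits$evalue < 0)) abort("negative E-value in hit table")
  if (!"coverage" %in% names(hits)) {
    hits$coverage <- hits$length / pmax(hits$qlen, hits$slen)
  }
  if (any(hits$coverage < 0 | hits$coverage > 1 + 1e-9)) {
    abort("hit coverage outside [0, 1]")
  }
  hits$coverage <- pmin(hits$coverage, 1)
  hits
}

#' Write a hit table as 14-column outfmt-6 TSV
#' @param hits Hit tibble (as from [hit_table()]).
#' @param path Output file.
#' @export
write_hits <- function(hits, path) {
  out <- tibble::tibble(
    q = hits$query, s = hits$subject, pident = hits$pident,
    length = hits$length, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = hits$length, sstart = 1L, send = hits$length,
    evalue = format(hits$evalue, scientific = TRUE, digits = 6),
    bitscore = round(-10 * log10(pmax(hits$evalue, 1e-300)), 1),
    qlen = hits$qlen, slen = hits$slen
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
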