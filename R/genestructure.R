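# Exon/intron junction mapping: CDS coordinates -> protein residues ->
# alignment columns -> consensus positions.

#' Construct a gene model from CDS exon intervals
#'
#' @param gene_id Gene identifier.
#' @param exons Tibble/data frame with `start`, `end` (1-based inclusive
#'   nucleotide coordinates, genomic orientation).
#' @param strand `"+"` or `"-"`.
#' @return A `gene_model` list: exons ordered 5'->3' in transcription
#'   orientation, CDS length, protein length, `complete` flag (CDS length
#'   divisible by 3).
#' @export
gene_model <- function(gene_id, exons, strand = "+") {
  exons <- tibble::as_tibble(exons)[, c("start", "end")]
  if (any(exons$start > exons$end)) abort("exon with start > end")
  exons <- exons |> arrange(.data$start)
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    abort(sprintf("overlapping exons in gene model '%s'", gene_id))
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), ]
  cds_len <- sum(exons$end - exons$start + 1L)
  structure(list(gene_id = gene_id, strand = strand, exons = exons,
                 cds_length = cds_len,
                 protein_length = cds_len %/% 3L,
                 complete = cds_len %% 3L == 0L),
            class = "gene_model")
}

#' Read gene models from an exon TSV or GFF3 CDS features
#'
#' TSV columns: `gene_id, start, end, strand`. In GFF3, `CDS` features are
#' grouped by their `Parent` (or `ID`) attribute.
#'
#' @param path Input file; `.gff`/`.gff3` triggers GFF parsing.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    keep <- !startsWith(lines, "#") & nzchar(lines)
    m <- do.call(rbind, strsplit(lines[keep], "\t", fixed = TRUE))
    cds <- m[m[, 3L] == "CDS", , drop = FALSE]
    id <- sub("^.*(?:Parent|ID)=([^;]+).*$", "\\1", cds[, 9L])
    d <- tibble::tibble(gene_id = id, start = as.integer(cds[, 4L]),
                        end = as.integer(cds[, 5L]), strand = cds[, 7L])
  } else {
    d <- readr::read_tsv(path, show_col_types = FALSE)
  }
  lapply(split(d, d$gene_id), function(g) {
    gene_model(g$gene_id[1L], g[, c("start", "end")], g$strand[1L])
  })
}

#' Exon junctions of a gene model in protein coordinates
#'
#' One junction per internal exon boundary. A boundary at cumulative CDS
#' offset `n` (0-based from the CDS start, transcription orientation) maps
#' to residue `floor(n/3)` with phase `n mod 3`: phase-0 junctions are
#' assigned to the first residue of the downstream exon, phases 1-2 to the
#' interrupted codon's residue. Single-exon genes yield no junctions.
#'
#' @param m A `gene_model`.
#' @return Tibble `(offset, residue, phase)` (0-based residues).
#' @export
cds_junctions <- function(m) {
  stopifnot(inherits(m, "gene_model"))
  widths <- m$exons$end - m$exons$start + 1L
  if (length(widths) < 2L) {
    return(tibble::tibble(offset = integer(), residue = integer(),
                          phase = integer()))
  }
  off <- cumsum(widths)[-length(widths)]
  tibble::tibble(offset = off, residue = off %/% 3L, phase = off %% 3L)
}

#' Map junctions onto alignment and consensus coordinates
#'
#' Residue indices are carried to alignment columns by skipping the gap
#' columns of that sequence's aligned row; a junction lands on a consensus
#' position when its column's occupancy reaches the threshold, in which
#' case its consensus index is the rank of that column among consensus
#' columns.
#'
#' @param junctions Tibble from [cds_junctions()].
#' @param row_id Row (sequence id) of this gene in the alignment.
#' @param a An `aln` matrix containing `row_id`.
#' @param occupancy Consensus occupancy threshold, default 0.7.
#' @return A `junction_map` tibble: offset, residue, phase, column (1-based),
#'   consensus (1-based index among consensus columns, `NA` if the column
#'   is below threshold).
#' @export
junctions_to_columns <- function(junctions, row_id, a, occupancy = 0.7) {
  if (!row_id %in% rownames(a)) {
    abort(sprintf("sequence '%s' not in alignment", row_id))
  }
  row <- unclass(a)[row_id, ]
  occ_cols <- which(!row %in% GAP_CHARS)
  if (nrow(junctions) && max(junctions$residue) + 1L > length(occ_cols)) {
    abort(sprintf(
      "junction residue %d beyond end of aligned sequence '%s' (%d residues); truncated gene model?",
      max(junctions$residue), row_id, length(occ_cols)))
  }
  cons <- consensus_columns(a, occupancy)
  col <- occ_cols[junctions$residue + 1L]
  consensus <- match(col, cons)
  out <- tibble::tibble(offset = junctions$offset,
                        residue = junctions$residue,
                        phase = junctions$phase,
                        column = col, consensus = consensus)
  structure(out, row_id = row_id,
            class = c("junction_map", class(tibble::tibble())))
}

#' Junction counts per consensus column
#'
#' @param maps List of `junction_map` tibbles on the same alignment.
#' @param a The alignment.
#' @param occupancy Consensus occupancy threshold, default 0.7.
#' @return Tibble `(consensus, column, count)` covering every consensus
#'   column (zero counts included).
#' @export
junction_column_counts <- function(maps, a, occupancy = 0.7) {
  cons <- consensus_columns(a, occupancy)
  counts <- integer(length(cons))
  for (m in maps) {
    ci <- m$consensus[!is.na(m$consensus)]
    for (i in ci) counts[i] <- counts[i] + 1L
  }
  tibble::tibble(consensus = seq_along(cons), column = cons, count = counts)
}

#' Binary junction features for the clade-association scan
#'
#' Feature `j<c>` fires for a gene when it has a junction within
#' `tolerance` consensus columns of consensus position `c`. The resulting
#' table plugs directly into [clade_chg_scan()].
#'
#' @param maps Named list of `junction_map` tibbles (names = gene ids).
#' @param tolerance Consensus-column tolerance, default 0.
#' @return Tibble `(focal, feature)` of present pairs.
#' @export
junction_clade_features <- function(maps, tolerance = 0) {
  pos <- sort(unique(unlist(lapply(maps, function(m) {
    m$consensus[!is.na(m$consensus)]
  }))))
  if (!length(pos)) {
    return(tibble::tibble(focal = character(), feature = character()))
  }
  purrr::map_dfr(names(maps), function(g) {
    ci <- maps[[g]]$consensus
    ci <- ci[!is.na(ci)]
    if (!length(ci)) return(NULL)
    hit <- pos[vapply(pos, function(p) any(abs(ci - p) <= tolerance),
                      logical(1))]
    tibble::tibble(focal = g, feature = paste0("j", hit))
  })
}
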