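## Homologous segments between the mitogenome and another genome (plastome
## for MTPT, nuclear contigs for NUMT).  Same ungapped seed-and-chain engine
## as the dispersed-repeat scan, applied across two genomes; no E-value
## statistics, filtering is by length and identity.

#' Find homologous segments between two genomes
#'
#' @param mito Query [genome_config()] (the mitogenome for the MTPT preset;
#'   nuclear contigs may equally be used as the query for NUMT scans).
#' @param other Subject [genome_config()] (plastome or mitogenome).
#' @param min_length Minimum segment length, bp; hits shorter than this are
#'   excluded (default 100, the conventional MTPT cutoff).
#' @param min_identity Minimum percent identity (default 70).
#' @param seed_size Exact k-mer seed (default 11).
#' @param orientations Which strand comparisons to run (both by default).
#' @return data.frame: `query_chrom, q_start, q_end, subject_chrom, s_start,
#'   s_end, length, identity, orientation, score`.  For inverted hits
#'   `s_start > s_end`.
#' @export
find_homologous_segments <- function(mito, other, min_length = 100,
                                     min_identity = 70, seed_size = 11,
                                     orientations = c("direct", "inverted")) {
  stopifnot(inherits(mito, "mito_config"), inherits(other, "mito_config"))
  if (!length(mito$chromosomes) || !length(other$chromosomes))
    stop("empty input genome")
  rows <- list()
  for (qc in mito$chromosomes) for (sc in other$chromosomes) {
    for (orient in orientations) {
      ali <- pair_alignments(qc$sequence, sc$sequence, orient, min_length,
                             min_identity, seed_size, self_same = FALSE)
      if (is.null(ali)) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_chrom = qc$id, q_start = ali$u1_start, q_end = ali$u1_end,
        subject_chrom = sc$id,
        s_start = if (orient == "inverted") ali$u2_end else ali$u2_start,
        s_end   = if (orient == "inverted") ali$u2_start else ali$u2_end,
        length = ali$len,
        identity = round(100 * (ali$len - ali$mism) / ali$len, 3),
        orientation = orient,
        score = 2L * (ali$len - ali$mism) - 3L * ali$mism,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(query_chrom = character(0), q_start = integer(0),
                      q_end = integer(0), subject_chrom = character(0),
                      s_start = integer(0), s_end = integer(0),
                      length = integer(0), identity = numeric(0),
                      orientation = character(0), score = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$length, out$query_chrom, out$q_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize transferred segments
#'
#' Overlapping query segments are not merged: `total_bp` is the plain sum,
#' so segments recurring in plastome inverted-repeat copies count twice, as
#' in conventional MTPT bookkeeping.
#'
#' @param segments A [find_homologous_segments()] table (or anything with a
#'   `length` column), or a numeric vector of segment lengths.
#' @param mito_length Total mitogenome length, bp.
#' @return List of class `mito_transfer_summary`: `n_segments, total_bp,
#'   fraction_percent` (rounded to 2 decimals), `longest_bp, shortest_bp`.
#' @export
summarize_transfers <- function(segments, mito_length) {
  stopifnot(mito_length > 0)
  lens <- if (is.numeric(segments)) segments else segments$length
  if (!length(lens))
    return(structure(list(n_segments = 0L, total_bp = 0L,
                          fraction_percent = 0, longest_bp = 0L,
                          shortest_bp = 0L),
                     class = "mito_transfer_summary"))
  structure(list(n_segments = length(lens), total_bp = sum(lens),
                 fraction_percent = round(100 * sum(lens) / mito_length, 2),
                 longest_bp = max(lens), shortest_bp = min(lens)),
            class = "mito_transfer_summary")
}

#' @export
print.mito_transfer_summary <- function(x, ...) {
  cat(sprintf("<mito_transfer_summary> %d segments, %s bp (%.2f%%), longest %s, shortest %s\n",
              x$n_segments, format(x$total_bp, big.mark = ","),
              x$fraction_percent, format(x$longest_bp, big.mark = ","),
              format(x$shortest_bp, big.mark = ",")))
  invisible(x)
}

#' Classify subject-genome genes by transfer completeness
#'
#' A gene is `complete` when some segment's subject interval fully contains
#' it, `partial` when properly overlapped, `absent` otherwise.
#'
#' @param segments A [find_homologous_segments()] table.
#' @param annotation List of [gene_model()]s on the subject genome (exon
#'   spans are pooled into the gene's full span).
#' @return data.frame: `gene_id, chrom, start, end, status`.
#' @export
classify_transferred_genes <- function(segments, annotation) {
  res <- lapply(annotation, function(g) {
    gs <- min(g$exons$start); ge <- max(g$exons$end)
    seg <- segments[segments$subject_chrom == g$chrom, , drop = FALSE]
    status <- "absent"
    if (nrow(seg)) {
      lo <- pmin(seg$s_start, seg$s_end)
      hi <- pmax(seg$s_start, seg$s_end)
      if (any(lo <= gs & hi >= ge)) status <- "complete"
      else if (any(lo <= ge & hi >= gs)) status <- "partial"
    }
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = gs, end = ge,
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a homologous-segment table as TSV
#' @param segments A [find_homologous_segments()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_tsv <- function(segments, path) {
  write.table(segments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
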