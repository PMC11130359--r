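#' Create a circular (or linear) chromosome
#'
#' The basic sequence unit of a genome configuration.  Plant mitogenomes are
#' typically multipartite: one configuration holds one or more circular
#' chromosomes that interconvert by repeat-mediated recombination.
#'
#' @param id Chromosome identifier (single string).
#' @param sequence DNA string over the alphabet `A,C,G,T,N` (case-insensitive;
#'   stored uppercase).
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `mito_chrom` with fields `id`, `sequence`,
#'   `topology` and `length`.
#' @examples
#' chromosome("c1", "ACGTACGT")
#' @export
chromosome <- function(id, sequence, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("chromosome '", id, "': empty sequence")
  bad <- regmatches(sequence, regexpr("[^ACGTN]", sequence))
  if (length(bad) && nzchar(bad))
    stop("chromosome '", id, "': illegal character '", bad, "'")
  structure(list(id = id, sequence = sequence, topology = topology,
                 length = nchar(sequence)),
            class = "mito_chrom")
}

#' @export
print.mito_chrom <- function(x, ...) {
  cat(sprintf("<mito_chrom> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Assemble chromosomes into a genome configuration
#'
#' A configuration is one particular arrangement of the mitogenome, e.g. the
#' predominant ("major") two-circle arrangement or a recombination-derived
#' ("minor") alternative.
#'
#' @param chromosomes A list of [chromosome()] objects (a single chromosome is
#'   also accepted).
#' @param name Configuration name, e.g. `"Mac"` or `"Mic1"`.
#' @param provenance Optional list recording how the configuration arose
#'   (parent configuration name and mediating repeat id).
#' @return An object of class `mito_config`.
#' @export
genome_config <- function(chromosomes, name = "config", provenance = NULL) {
  if (inherits(chromosomes, "mito_chrom")) chromosomes <- list(chromosomes)
  stopifnot(length(chromosomes) >= 1L,
            all(vapply(chromosomes, inherits, logical(1), "mito_chrom")))
  ids <- vapply(chromosomes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate chromosome ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(chromosomes) <- ids
  structure(list(name = name, chromosomes = chromosomes,
                 provenance = provenance),
            class = "mito_config")
}

#' @export
print.mito_config <- function(x, ...) {
  cat(sprintf("<mito_config> %s: %d chromosome(s), %s bp total\n", x$name,
              length(x$chromosomes),
              format(config_length(x), big.mark = ",")))
  for (ch in x$chromosomes)
    cat(sprintf("  %s  %s bp  %s\n", ch$id,
                format(ch$length, big.mark = ","), ch$topology))
  invisible(x)
}

#' Total length of a genome configuration
#' @param config A [genome_config()] object.
#' @return Integer total bp.
#' @export
config_length <- function(config) {
  sum(vapply(config$chromosomes, `[[`, numeric(1), "length"))
}

#' Create a (possibly origin-wrapping) genomic interval
#'
#' Coordinates are 1-based and inclusive at both ends, matching the convention
#' of published repeat tables.  On a circular chromosome `start > end` denotes
#' an interval that wraps through the origin.
#'
#' @param chrom Chromosome identifier the interval refers to.
#' @param start,end 1-based inclusive positions.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `mito_interval`.
#' @export
interval <- function(chrom, start, end, strand = "+") {
  stopifnot(strand %in% c("+", "-"), start >= 1L, end >= 1L)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "mito_interval")
}

#' Length spanned by an interval on a chromosome of given size
#' @param iv A [interval()]; `chrom_len` the chromosome length.
#' @return Integer bp, wrap-corrected.
#' @export
interval_length <- function(iv, chrom_len) {
  if (iv$start <= iv$end) iv$end - iv$start + 1L
  else chrom_len - iv$start + 1L + iv$end
}

#' Reverse complement of DNA strings
#'
#' Watson-Crick complement, reversed; `N` is self-complementary.  Vectorised.
#'
#' @param seq Character vector of DNA strings over `A,C,G,T,N`.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("ATGCN")  # "NGCAT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) stop("unknown character in sequence ", which(bad)[1])
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# Internal: circular substring [start, start+len-1] with wrap.
circ_substr <- function(s, start, len) {
  n <- nchar(s)
  start <- ((start - 1L) %% n) + 1L
  if (len <= 0L) return("")
  if (len > n) stop("requested length exceeds chromosome length")
  end <- start + len - 1L
  if (end <= n) substr(s, start, end)
  else paste0(substr(s, start, n), substr(s, 1L, end - n))
}

#' Extract the sequence of an interval from a chromosome
#'
#' Wrap through the origin (`start > end`) is permitted only on circular
#' chromosomes.  Strand `"-"` returns the reverse complement of the
#' plus-strand sequence.
#'
#' @param chrom A [chromosome()].
#' @param iv A [interval()] on that chromosome.
#' @return DNA string.
#' @examples
#' extract_subsequence(chromosome("c", "ACGTACGT"), interval("c", 7, 2))
#' @export
extract_subsequence <- function(chrom, iv) {
  stopifnot(inherits(chrom, "mito_chrom"), inherits(iv, "mito_interval"))
  if (!identical(iv$chrom, chrom$id))
    stop("interval chrom '", iv$chrom, "' does not match chromosome '",
         chrom$id, "'")
  n <- chrom$length
  if (iv$start > n || iv$end > n)
    stop("interval [", iv$start, ",", iv$end, "] out of range for '",
         chrom$id, "' (", n, " bp)")
  if (iv$start > iv$end && chrom$topology != "circular")
    stop("origin wrap requested on linear chromosome '", chrom$id, "'")
  len <- interval_length(iv, n)
  s <- circ_substr(chrom$sequence, iv$start, len)
  if (iv$strand == "-") reverse_complement(s) else s
}

#' Rotate a circular chromosome
#'
#' The former position `offset + 1` becomes position 1.  Rotation by 0 or by
#' the chromosome length is the identity.
#'
#' @param chrom A circular [chromosome()].
#' @param offset Integer rotation offset (any integer; reduced mod length).
#' @return A new `mito_chrom` of the same id, length and topology.
#' @export
rotate <- function(chrom, offset) {
  stopifnot(inherits(chrom, "mito_chrom"))
  if (chrom$topology != "circular")
    stop("rotation requested on linear chromosome '", chrom$id, "'")
  n <- chrom$length
  off <- ((as.integer(offset)) %% n)
  if (off == 0L) return(chrom)
  chromosome(chrom$id,
             paste0(substr(chrom$sequence, off + 1L, n),
                    substr(chrom$sequence, 1L, off)),
             chrom$topology)
}

# Internal: Booth's least-rotation index (0-based offset of the
# lexicographically minimal rotation).
least_rotation_offset <- function(s) {
  n <- nchar(s)
  v <- utf8ToInt(paste0(s, s))
  f <- rep.int(-1L, 2L * n)
  k <- 0L
  for (j in 2:(2L * n)) {
    sj <- v[j]
    i <- f[j - k - 1L]
    while (i != -1L && sj != v[k + i + 2L]) {
      if (sj < v[k + i + 2L]) k <- j - i - 2L
      i <- f[i + 1L]
    }
    if (sj != v[k + i + 2L]) {
      if (sj < v[k + 1L]) k <- j - 1L
      f[j - k] <- -1L
    } else f[j - k] <- i + 1L
  }
  k
}

#' Canonicalize a circular chromosome to its minimal rotation
#'
#' Rotates so that the sequence is the lexicographically smallest of all its
#' rotations; makes recombination products deterministic and comparable.
#'
#' @param chrom A circular [chromosome()].
#' @return A rotated `mito_chrom`.
#' @export
canonical_rotation <- function(chrom) {
  if (chrom$topology != "circular") return(chrom)
  rotate(chrom, least_rotation_offset(chrom$sequence))
}

#' Base composition of a genome configuration
#'
#' Per-chromosome and pooled counts of A, C, G, T and N, proportions, and GC
#' percentage.  By default N bases stay in the GC denominator (so a genome
#' with Ns reports a slightly lower GC); set `exclude_n = TRUE` to divide by
#' A+C+G+T only.
#'
#' @param config A [genome_config()].
#' @param exclude_n Drop N from the GC denominator (default `FALSE`).
#' @return A data.frame of class `mito_composition`, one row per chromosome
#'   plus a pooled `"total"` row; columns `chrom,total,A,C,G,T,N,gc_percent`.
#' @examples
#' base_composition(genome_config(chromosome("c", "GGCC")))
#' @export
base_composition <- function(config, exclude_n = FALSE) {
  stopifnot(inherits(config, "mito_config"))
  seqs <- vapply(config$chromosomes, `[[`, character(1), "sequence")
  af <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(seqs),
                                      baseOnly = TRUE)
  m <- rbind(af, colSums(af))
  rows <- c(names(config$chromosomes), "total")
  denom <- m[, "A"] + m[, "C"] + m[, "G"] + m[, "T"] +
    if (exclude_n) 0 else m[, "other"]
  out <- data.frame(
    chrom = rows,
    total = rowSums(m),
    A = m[, "A"], C = m[, "C"], G = m[, "G"], T = m[, "T"],
    N = m[, "other"],
    gc_percent = 100 * (m[, "G"] + m[, "C"]) / denom,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("mito_composition", class(out))
  out
}

#' Write a composition report as TSV
#' @param x A [base_composition()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
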