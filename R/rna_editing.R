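## C-to-U RNA editing calling from base pileups, with DNA-level SNP masking
## and codon-consequence annotation.  Plant mitochondria translate with the
## standard genetic code, which is what makes the canonical ACG->AUG start
## gain and UAA/UAG/UGA stop gains reachable by a single C->U edit.

#' Create a gene model
#'
#' Exons are given in transcription order (which for trans-spliced genes may
#' differ from genomic order); minus-strand exons are reverse-complemented on
#' extraction.
#'
#' @param gene_id Gene identifier (append a copy suffix for duplicated
#'   genes, e.g. `"atp6.copy2"`).
#' @param chrom Chromosome id.
#' @param exons A data.frame with `start`, `end` (1-based inclusive), or a
#'   list of [interval()]s.
#' @param strand `"+"` or `"-"`.
#' @param codon_start Phase offset (0 default).
#' @return An object of class `mito_gene`.
#' @export
gene_model <- function(gene_id, chrom, exons, strand = "+", codon_start = 0L) {
  stopifnot(strand %in% c("+", "-"))
  if (is.list(exons) && !is.data.frame(exons) &&
      all(vapply(exons, inherits, logical(1), "mito_interval")))
    exons <- data.frame(start = vapply(exons, `[[`, integer(1), "start"),
                        end = vapply(exons, `[[`, integer(1), "end"))
  stopifnot(is.data.frame(exons), nrow(exons) >= 1L,
            all(exons$start <= exons$end))
  structure(list(gene_id = gene_id, chrom = chrom,
                 exons = exons[, c("start", "end"), drop = FALSE],
                 strand = strand, codon_start = as.integer(codon_start)),
            class = "mito_gene")
}

#' Spliced CDS sequence of a gene
#'
#' @param gene A [gene_model()].
#' @param genome A [genome_config()].
#' @return DNA string (coding strand).
#' @export
build_cds <- function(gene, genome) {
  stopifnot(inherits(gene, "mito_gene"), inherits(genome, "mito_config"))
  ch <- genome$chromosomes[[gene$chrom]]
  if (is.null(ch)) stop("gene '", gene$gene_id, "' references unknown chromosome '",
                        gene$chrom, "'")
  if (any(gene$exons$end > ch$length)) stop("exon out of range for '",
                                            gene$gene_id, "'")
  parts <- vapply(seq_len(nrow(gene$exons)), function(i) {
    extract_subsequence(ch, interval(gene$chrom, gene$exons$start[i],
                                     gene$exons$end[i], gene$strand))
  }, character(1))
  cds <- paste(parts, collapse = "")
  if (nchar(cds) %% 3L != 0L)
    warning("CDS length of '", gene$gene_id, "' not divisible by 3")
  cds
}

# Internal: genomic position of each base of the spliced CDS, coding-strand
# order.  Minus-strand exons run from end down to start.
cds_genomic_positions <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$exons)), function(i) {
    if (gene$strand == "+") gene$exons$start[i]:gene$exons$end[i]
    else gene$exons$end[i]:gene$exons$start[i]
  }))
  as.integer(pos)
}

#' Call DNA-level variants to build an SNP mask
#'
#' A position is masked when its DNA coverage reaches `min_cov` and any
#' non-reference base reaches frequency `min_freq`.  Masked positions are
#' never reported as RNA editing (a genomic SNP would mimic an edit).
#'
#' @param pileups A pileup data.frame (`chrom, pos, ref, A, C, G, T`,
#'   optional `source`); rows with `source != "DNA"` are ignored when the
#'   column is present.
#' @param min_cov Minimum coverage (default 5).
#' @param min_freq Minimum minor-allele frequency (default 0.1).
#' @return data.frame `chrom, pos` of masked positions (class
#'   `mito_snp_mask`).
#' @export
call_dna_variants <- function(pileups, min_cov = 5L, min_freq = 0.1) {
  p <- pileups
  if ("source" %in% names(p)) p <- p[p$source == "DNA", , drop = FALSE]
  if (!nrow(p)) {
    out <- data.frame(chrom = character(0), pos = integer(0))
    class(out) <- c("mito_snp_mask", class(out)); return(out)
  }
  cov <- p$A + p$C + p$G + p$T
  refmat <- cbind(A = p$A, C = p$C, G = p$G, T = p$T)
  # max non-reference count per row
  alt_max <- vapply(seq_len(nrow(p)), function(i) {
    z <- refmat[i, ]
    if (p$ref[i] %in% names(z)) z[p$ref[i]] <- 0L
    max(z)
  }, numeric(1))
  hit <- cov >= min_cov & cov > 0 & alt_max / cov >= min_freq
  out <- unique(data.frame(chrom = p$chrom[hit], pos = p$pos[hit]))
  rownames(out) <- NULL
  class(out) <- c("mito_snp_mask", class(out))
  out
}

#' Call C-to-U RNA editing sites
#'
#' A site is called when (i) it lies in a spliced CDS, (ii) the coding-strand
#' reference base is C (genomic C for plus-strand genes, genomic G for
#' minus-strand genes), (iii) RNA coverage is at least `min_cov`, (iv) the
#' editing extent `edited / (edited + unedited)` is at least `min_freq`,
#' where on the genome plus strand edited/unedited read as T/C for plus
#' genes and A/G for minus genes, and (v) the position is not SNP-masked.
#' Bases other than the edited/unedited pair are treated as sequencing error
#' and excluded from the extent denominator.
#'
#' @param rna_pileups Pileup data.frame (`chrom, pos, ref, A, C, G, T`,
#'   optional `source`; rows with `source != "RNA"` ignored when present).
#' @param genes List of [gene_model()]s.
#' @param genome A [genome_config()].
#' @param mask Optional [call_dna_variants()] mask.
#' @param min_cov,min_freq Calling thresholds (defaults 5 and 0.1).
#' @return data.frame of editing sites: `gene_id, chrom, genomic_pos,
#'   cds_pos, codon_index, codon_pos, ref_codon, edited_codon, ref_aa,
#'   edited_aa, extent, effect, hydropathy_shift`.
#' @export
call_editing_sites <- function(rna_pileups, genes, genome, mask = NULL,
                               min_cov = 5L, min_freq = 0.1) {
  p <- rna_pileups
  if ("source" %in% names(p)) p <- p[p$source == "RNA", , drop = FALSE]
  masked <- if (!is.null(mask) && nrow(mask))
    paste(mask$chrom, mask$pos) else character(0)
  key <- paste(p$chrom, p$pos)
  out <- list()
  for (g in genes) {
    ch <- genome$chromosomes[[g$chrom]]
    if (is.null(ch)) stop("gene '", g$gene_id, "' references unknown chromosome")
    cds <- suppressWarnings(build_cds(g, genome))
    gpos <- cds_genomic_positions(g)
    cpos <- which(strsplit(cds, "", fixed = TRUE)[[1]] == "C")
    if (!length(cpos)) next
    rows <- match(paste(g$chrom, gpos[cpos]), key)
    for (t in seq_along(cpos)) {
      i <- rows[t]
      if (is.na(i)) next
      if (g$strand == "+") { ed <- p$T[i]; un <- p$C[i] }
      else { ed <- p$A[i]; un <- p$G[i] }
      cov <- p$A[i] + p$C[i] + p$G[i] + p$T[i]
      if (cov < min_cov || ed + un == 0L) next
      extent <- ed / (ed + un)
      if (extent < min_freq) next
      if (paste(g$chrom, gpos[cpos[t]]) %in% masked) next
      site <- annotate_effect(
        list(gene_id = g$gene_id, chrom = g$chrom,
             genomic_pos = gpos[cpos[t]], cds_pos = cpos[t],
             extent = extent), cds)
      out[[length(out) + 1L]] <- as.data.frame(site,
                                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      genomic_pos = integer(0), cds_pos = integer(0),
                      codon_index = integer(0), codon_pos = integer(0),
                      ref_codon = character(0), edited_codon = character(0),
                      ref_aa = character(0), edited_aa = character(0),
                      extent = numeric(0), effect = character(0),
                      hydropathy_shift = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

HYDROPHOBIC_AA <- c("A", "C", "F", "I", "L", "M", "V")  # Kyte-Doolittle > 0

# Internal: translate one codon with the standard code; "*" for stop.
translate_codon <- function(codon) {
  if (grepl("N", codon)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate the codon-level consequence of a C-to-U edit
#'
#' Classifies the edit as `synonymous`, `nonsynonymous`, `stop_gain`,
#' `start_gain` (first codon becoming ATG, canonically ACG -> AUG) or
#' `stop_loss`, and records the hydropathy shift of a nonsynonymous change
#' (hydrophobic set A, C, F, I, L, M, V).
#'
#' @param site A list or one-row data.frame with at least `cds_pos` (plus
#'   any identifying fields, which are carried through).
#' @param cds The gene's spliced CDS (coding strand).
#' @return `site` as a list extended with `codon_index, codon_pos,
#'   ref_codon, edited_codon, ref_aa, edited_aa, effect, hydropathy_shift`.
#' @export
annotate_effect <- function(site, cds) {
  site <- as.list(site)
  pos <- as.integer(site$cds_pos)
  if (pos < 1L || pos > nchar(cds)) stop("cds_pos outside CDS")
  if (substr(cds, pos, pos) != "C")
    stop("cds_pos ", pos, " is not a C on the coding strand")
  codon_index <- (pos - 1L) %/% 3L + 1L
  codon_pos <- (pos - 1L) %% 3L + 1L
  cstart <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substr(cds, cstart, cstart + 2L)
  edited_codon <- ref_codon
  substr(edited_codon, codon_pos, codon_pos) <- "T"
  ref_aa <- translate_codon(ref_codon)
  edited_aa <- translate_codon(edited_codon)
  stops <- c("TAA", "TAG", "TGA")
  effect <- if (is.na(ref_aa) || is.na(edited_aa)) "undetermined"
    else if (codon_index == 1L && edited_codon == "ATG" &&
             ref_codon != "ATG") "start_gain"
    else if (edited_codon %in% stops && !(ref_codon %in% stops)) "stop_gain"
    else if (ref_codon %in% stops && !(edited_codon %in% stops)) "stop_loss"
    else if (ref_aa == edited_aa) "synonymous"
    else "nonsynonymous"
  hyd <- "none"
  if (effect == "nonsynonymous") {
    rh <- ref_aa %in% HYDROPHOBIC_AA
    eh <- edited_aa %in% HYDROPHOBIC_AA
    if (!rh && eh) hyd <- "hydrophilic->hydrophobic"
    if (rh && !eh) hyd <- "hydrophobic->hydrophilic"
  }
  c(site, list(codon_index = codon_index, codon_pos = codon_pos,
               ref_codon = ref_codon, edited_codon = edited_codon,
               ref_aa = ref_aa, edited_aa = edited_aa,
               effect = effect, hydropathy_shift = hyd))
}

#' Summarize editing sites
#'
#' @param sites A [call_editing_sites()] table.
#' @return List: `per_gene` (gene -> site count), `aa_changes`
#'   ((ref_aa, edited_aa) -> count), `codon_positions` (counts at codon
#'   positions 1/2/3), `effects` (effect class counts), `total`.
#' @export
summarize_editing <- function(sites) {
  if (is.null(sites) || !nrow(sites))
    return(list(per_gene = integer(0),
                aa_changes = data.frame(ref_aa = character(0),
                                        edited_aa = character(0),
                                        n = integer(0)),
                codon_positions = setNames(integer(3), 1:3),
                effects = integer(0), total = 0L))
  per_gene <- table(sites$gene_id)
  aa <- aggregate(list(n = seq_len(nrow(sites))),
                  by = list(ref_aa = sites$ref_aa,
                            edited_aa = sites$edited_aa), FUN = length)
  cp <- table(factor(sites$codon_pos, levels = 1:3))
  list(per_gene = setNames(as.integer(per_gene), names(per_gene)),
       aa_changes = aa[order(-aa$n, aa$ref_aa), ],
       codon_positions = setNames(as.integer(cp), 1:3),
       effects = setNames(as.integer(table(sites$effect)),
                          names(table(sites$effect))),
       total = nrow(sites))
}

#' Write an editing-site table as TSV
#' @param sites A [call_editing_sites()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_editing_tsv <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
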