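test_that("build_cds extracts strand-aware spliced CDS in listed order", {
  g <- genome_config(chromosome("c", "ATGTAACCGGTT"))
  plus <- gene_model("g1", "c", data.frame(start = 1, end = 6), "+")
  expect_equal(build_cds(plus, g), "ATGTAA")
  minus <- gene_model("g2", "c", data.frame(start = 1, end = 6), "-")
  expect_equal(build_cds(minus, g), reverse_complement("ATGTAA"))
  # trans-spliced order: the exon listed first comes first in the CDS even
  # though it lies downstream in the genome
  trans <- gene_model("g3", "c", data.frame(start = c(7, 1), end = c(12, 6)),
                      "+")
  expect_equal(build_cds(trans, g), "CCGGTTATGTAA")
  expect_error(build_cds(gene_model("g4", "c",
                                    data.frame(start = 1, end = 15)), g),
               "out of range")
  expect_error(build_cds(gene_model("g5", "zz",
                                    data.frame(start = 1, end = 3)), g),
               "unknown chromosome")
  expect_warning(build_cds(gene_model("g6", "c",
                                      data.frame(start = 1, end = 4)), g),
                 "divisible by 3")
})

test_that("call_dna_variants applies coverage and frequency thresholds", {
  pile <- function(A = 0, C = 0, G = 0, T = 0, ref = "C")
    data.frame(chrom = "c", pos = 10, ref = ref, A = A, C = C, G = G, T = T,
               source = "DNA")
  expect_equal(nrow(call_dna_variants(pile(C = 5, T = 5))), 1)   # freq 0.5
  expect_equal(nrow(call_dna_variants(pile(C = 9))), 0)          # no alt
  expect_equal(nrow(call_dna_variants(pile(C = 3, T = 1))), 0)   # cov 4 < 5
  expect_equal(nrow(call_dna_variants(pile(C = 9, T = 1))), 1)   # freq 0.10
  expect_equal(nrow(call_dna_variants(pile(C = 19, T = 1))), 0)  # freq 0.05
  # RNA rows are ignored when a source column is present
  p <- pile(C = 5, T = 5); p$source <- "RNA"
  expect_equal(nrow(call_dna_variants(p)), 0)
})

test_that("call_editing_sites enforces all five calling conditions", {
  g <- genome_config(chromosome("c", "ATGCCACAATAG"))   # M P Q *
  gene <- gene_model("g1", "c", data.frame(start = 1, end = 12), "+")
  rna <- function(pos, A = 0, C = 0, G = 0, T = 0)
    data.frame(chrom = "c", pos = pos, ref = substr("ATGCCACAATAG", pos, pos),
               A = A, C = C, G = G, T = T, source = "RNA")
  # called: C at CDS pos 4, coverage 10, extent 0.4
  got <- call_editing_sites(rna(4, C = 6, T = 4), list(gene), g)
  expect_equal(nrow(got), 1)
  expect_equal(got$extent, 0.4)
  expect_equal(got$cds_pos, 4)
  # below frequency threshold
  expect_equal(nrow(call_editing_sites(rna(4, C = 19, T = 1), list(gene), g)), 0)
  # below coverage threshold
  expect_equal(nrow(call_editing_sites(rna(4, C = 2, T = 2), list(gene), g)), 0)
  # reference base not C: position 1 is A
  expect_equal(nrow(call_editing_sites(rna(1, A = 5, T = 5), list(gene), g)), 0)
  # masked position is never called
  mask <- data.frame(chrom = "c", pos = 4)
  class(mask) <- c("mito_snp_mask", class(mask))
  expect_equal(nrow(call_editing_sites(rna(4, C = 5, T = 5), list(gene), g,
                                       mask = mask)), 0)
  # extent denominator is C+T only: G reads are error, extent = 4/(4+4)
  got2 <- call_editing_sites(rna(4, C = 4, T = 4, G = 2), list(gene), g)
  expect_equal(got2$extent, 0.5)
})

test_that("minus-strand genes read the edit as G->A on the genome", {
  # coding strand CDS "ATGCAATAA" lies reverse-complemented on the genome
  cds <- "ATGCAATAA"
  gseq <- paste0("GGGG", reverse_complement(cds), "GGGG")
  g <- genome_config(chromosome("c", gseq))
  gene <- gene_model("g1", "c", data.frame(start = 5, end = 13), "-")
  expect_equal(build_cds(gene, g), cds)
  # CDS position 4 is C; genomic base there is G at position 13 - 3 = 10
  gpos <- 13 - (4 - 1)
  expect_equal(substr(gseq, gpos, gpos), "G")
  rna <- data.frame(chrom = "c", pos = gpos, ref = "G",
                    A = 4, C = 0, G = 6, T = 0, source = "RNA")
  got <- call_editing_sites(rna, list(gene), g)
  expect_equal(nrow(got), 1)
  expect_equal(got$extent, 0.4)
  expect_equal(got$genomic_pos, gpos)
  expect_equal(got$ref_codon, "CAA")
  expect_equal(got$edited_codon, "TAA")
  expect_equal(got$effect, "stop_gain")
})

test_that("annotate_effect matches an exhaustive translation oracle", {
  # oracle translation via Biostrings::translate on DNAStringSet, a separate
  # code path from the GENETIC_CODE lookup used by the implementation
  oracle_aa <- function(codon)
    as.character(Biostrings::translate(Biostrings::DNAStringSet(codon)))
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  hydro <- c("A", "C", "F", "I", "L", "M", "V")
  n_checked <- 0
  for (codon in codons) for (cp in 1:3) {
    if (substr(codon, cp, cp) != "C") next
    for (first in c(TRUE, FALSE)) {
      cds <- if (first) paste0(codon, "GGGTAA") else paste0("ATG", codon, "TAA")
      pos <- if (first) cp else 3 + cp
      site <- annotate_effect(list(gene_id = "g", cds_pos = pos), cds)
      edited <- codon
      substr(edited, cp, cp) <- "T"
      want <- if (first && edited == "ATG" && codon != "ATG") "start_gain"
        else if (edited %in% stops && !(codon %in% stops)) "stop_gain"
        else if (codon %in% stops && !(edited %in% stops)) "stop_loss"
        else if (oracle_aa(codon) == oracle_aa(edited)) "synonymous"
        else "nonsynonymous"
      expect_equal(site$effect, want,
                   info = paste(codon, cp, if (first) "first" else "internal"))
      expect_equal(site$ref_codon, codon)
      expect_equal(site$edited_codon, edited)
      if (want == "nonsynonymous") {
        rh <- oracle_aa(codon) %in% hydro; eh <- oracle_aa(edited) %in% hydro
        wanth <- if (!rh && eh) "hydrophilic->hydrophobic"
          else if (rh && !eh) "hydrophobic->hydrophilic" else "none"
        expect_equal(site$hydropathy_shift, wanth, info = paste(codon, cp))
      } else {
        expect_equal(site$hydropathy_shift, "none")
      }
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 96)   # 48 C-containing codon/position pairs x 2
  # the named canonical cases
  expect_equal(annotate_effect(list(cds_pos = 2), "ACGTAA")$effect, "start_gain")
  expect_equal(annotate_effect(list(cds_pos = 4), "ATGCAATAA")$effect, "stop_gain")
  expect_equal(annotate_effect(list(cds_pos = 4), "ATGCGATAA")$effect, "stop_gain")
  expect_equal(annotate_effect(list(cds_pos = 4), "ATGCAGTAA")$effect, "stop_gain")
  expect_equal(annotate_effect(list(cds_pos = 6), "ATGATCTAA")$effect, "synonymous")
  expect_error(annotate_effect(list(cds_pos = 1), "ATG"), "not a C")
})

test_that("planted editing sites are recovered exactly at error rate 0", {
  sim <- generate_mitogenome(mitogenome_spec(seed = 21))
  genes <- sim$truth$genes
  set.seed(22)
  sites <- NULL
  for (g in genes) {
    cds <- build_cds(g, sim$config)
    cpos <- which(strsplit(cds, "")[[1]] == "C")
    pick <- sample(cpos, min(6, length(cpos)))
    sites <- rbind(sites, data.frame(gene_id = g$gene_id, cds_pos = pick,
                                     extent = runif(length(pick), 0.25, 0.95)))
  }
  plan <- editing_plan(sites, rna_depth = 40, dna_depth = 30,
                       error_rate = 0, seed = 23)
  pp <- simulate_editing_reads(sim$config, genes, plan)
  mask <- call_dna_variants(pp$dna)
  calls <- call_editing_sites(pp$rna, genes, sim$config, mask)
  key <- function(d) paste(d$gene_id, d$cds_pos)
  expect_setequal(key(calls), key(pp$truth))
  # every call satisfies the thresholds it was made under
  covs <- merge(calls, pp$rna, by.x = c("chrom", "genomic_pos"),
                by.y = c("chrom", "pos"))
  expect_true(all(covs$A + covs$C + covs$G + covs$T >= 5))
  expect_true(all(calls$extent >= 0.1))
  # all calls are C->U on the coding strand
  expect_true(all(substr(calls$ref_codon, calls$codon_pos,
                         calls$codon_pos) == "C"))
  expect_true(all(substr(calls$edited_codon, calls$codon_pos,
                         calls$codon_pos) == "T"))
  # extent estimates concentrate around truth
  m <- merge(calls, pp$truth, by = c("gene_id", "cds_pos"))
  expect_true(all(abs(m$extent.x - m$extent.y) <
                    3 * sqrt(m$extent.y * (1 - m$extent.y) / 20) + 0.05))
})

test_that("summarize_editing tallies genes, changes and codon positions", {
  empty <- summarize_editing(NULL)
  expect_equal(empty$total, 0)
  sites <- data.frame(
    gene_id = c("a", "a", "a", "b", "b"),
    ref_aa = c("P", "P", "S", "R", "T"),
    edited_aa = c("L", "L", "F", "W", "M"),
    codon_pos = c(2, 2, 1, 1, 2),
    effect = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
               "nonsynonymous", "nonsynonymous"))
  sm <- summarize_editing(sites)
  expect_equal(sm$total, 5)
  expect_equal(sm$per_gene, c(a = 3L, b = 2L))
  expect_equal(unname(sm$codon_positions), c(2L, 3L, 0L))
  pl <- sm$aa_changes[sm$aa_changes$ref_aa == "P", ]
  expect_equal(pl$n, 2)
})
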