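## Synthetic mitogenomes, long-read mixtures and editing pileups with
## planted truth.  The generator's defaults mirror the structure the
## pipeline is built for: a two-circle genome at GC ~0.45 carrying long
## (2-8 kb) near-identical (>= 99.9%) repeat pairs, scaled down ~10x in
## total size so every stage runs in seconds.

random_dna <- function(n, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Specification of a synthetic mitogenome
#'
#' @param chrom_lengths Chromosome lengths in bp (default two circles,
#'   50 kb and 10 kb).
#' @param gc_target Target GC fraction (default 0.45).
#' @param repeats data.frame of planted repeat pairs with columns `length`,
#'   `identity` (percent), `orientation` (`direct`/`inverted`), `chrom1`,
#'   `chrom2` (1-based chromosome indices).  Default: one 3 kb direct pair
#'   and one 2.8 kb inverted pair at 99.96% identity, both on chromosome 1.
#' @param ssrs data.frame of planted SSRs: `motif`, `copies`, `chrom`.
#' @param genes data.frame of planted genes: `length` (bp, multiple of 3),
#'   `strand`, `n_exons`, `chrom`.
#' @param seed Integer seed; the whole generator is deterministic given it.
#' @return List of class `mito_synth_spec`.
#' @export
mitogenome_spec <- function(chrom_lengths = c(50000L, 10000L),
                            gc_target = 0.45,
                            repeats = data.frame(
                              length = c(3000L, 2795L),
                              identity = c(100, 99.96),
                              orientation = c("direct", "inverted"),
                              chrom1 = c(1L, 1L), chrom2 = c(1L, 1L)),
                            ssrs = data.frame(
                              motif = c("A", "AT", "AGC", "AATC", "AACGT"),
                              copies = c(12L, 8L, 6L, 6L, 5L),
                              chrom = c(1L, 1L, 1L, 2L, 2L)),
                            genes = data.frame(
                              length = c(900L, 600L, 450L),
                              strand = c("+", "-", "+"),
                              n_exons = c(1L, 2L, 1L),
                              chrom = c(1L, 1L, 2L)),
                            seed = 1L) {
  structure(list(chrom_lengths = as.integer(chrom_lengths),
                 gc_target = gc_target, repeats = repeats, ssrs = ssrs,
                 genes = genes, seed = as.integer(seed)),
            class = "mito_synth_spec")
}

# Internal: allocate a free interval of length len on chromosome `ci`,
# avoiding `occupied[[ci]]` (data.frame start,end), with bounded retries.
alloc_interval <- function(occupied, ci, len, n, margin = 50L,
                           retries = 200L) {
  occ <- occupied[[ci]]
  for (t in seq_len(retries)) {
    st <- sample.int(n - len - margin, 1L) + margin %/% 2L
    en <- st + len - 1L
    if (!nrow(occ) || all(en + margin < occ$start | st - margin > occ$end))
      return(c(st, en))
  }
  stop("infeasible placement: no free interval of ", len, " bp on chromosome ",
       ci, " after ", retries, " retries")
}

#' Generate a synthetic mitogenome with planted truth
#'
#' Builds random circular chromosomes at the target GC, then plants repeat
#' pairs (copying a source locus, mutating random interior positions down to
#' the requested identity, reverse-complementing for inverted pairs), SSR
#' runs and protein-coding genes (ATG + non-stop codons + TAA, optionally
#' split into exons separated by ~100 bp introns).  Deterministic for a
#' fixed seed.
#'
#' @param spec A [mitogenome_spec()].
#' @return List: `config` (a [genome_config()]) and `truth` with elements
#'   `repeats`, `ssrs` (coordinate tables) and `genes` (list of
#'   [gene_model()]s plus a `gene_table`).
#' @export
generate_mitogenome <- function(spec = mitogenome_spec()) {
  stopifnot(inherits(spec, "mito_synth_spec"))
  set.seed(spec$seed)
  nchrom <- length(spec$chrom_lengths)
  seqs <- vapply(spec$chrom_lengths, random_dna, character(1),
                 gc = spec$gc_target)
  occupied <- replicate(nchrom,
                        data.frame(start = integer(0), end = integer(0)),
                        simplify = FALSE)
  note <- function(ci, st, en) {
    occupied[[ci]] <<- rbind(occupied[[ci]],
                             data.frame(start = st, end = en))
  }
  `write_at` <- function(ci, st, frag) {
    substr(seqs[ci], st, st + nchar(frag) - 1L) <<- frag
  }

  repeat_truth <- NULL
  if (!is.null(spec$repeats) && nrow(spec$repeats)) {
    for (i in seq_len(nrow(spec$repeats))) {
      r <- spec$repeats[i, ]
      len <- r$length
      p1 <- alloc_interval(occupied, r$chrom1, len, spec$chrom_lengths[r$chrom1])
      note(r$chrom1, p1[1], p1[2])
      unit <- substr(seqs[r$chrom1], p1[1], p1[2])
      nmut <- round(len * (100 - r$identity) / 100)
      if (nmut > 0) {
        mpos <- sample(2:(len - 1L), nmut)
        uv <- strsplit(unit, "", fixed = TRUE)[[1]]
        for (m in mpos)
          uv[m] <- sample(setdiff(c("A", "C", "G", "T"), uv[m]), 1L)
        unit <- paste(uv, collapse = "")
      }
      if (r$orientation == "inverted") unit <- reverse_complement(unit)
      p2 <- alloc_interval(occupied, r$chrom2, len, spec$chrom_lengths[r$chrom2])
      note(r$chrom2, p2[1], p2[2])
      write_at(r$chrom2, p2[1], unit)
      repeat_truth <- rbind(repeat_truth, data.frame(
        id = paste0("planted_rep", i), length = len, identity = r$identity,
        mismatches = nmut, orientation = r$orientation,
        unit1_chrom = paste0("chr", r$chrom1), unit1_start = p1[1],
        unit1_end = p1[2],
        unit2_chrom = paste0("chr", r$chrom2), unit2_start = p2[1],
        unit2_end = p2[2], stringsAsFactors = FALSE))
    }
  }

  ssr_truth <- NULL
  if (!is.null(spec$ssrs) && nrow(spec$ssrs)) {
    for (i in seq_len(nrow(spec$ssrs))) {
      s <- spec$ssrs[i, ]
      run <- strrep(s$motif, s$copies)
      p <- alloc_interval(occupied, s$chrom, nchar(run),
                          spec$chrom_lengths[s$chrom])
      note(s$chrom, p[1], p[2])
      write_at(s$chrom, p[1], run)
      # guard rails so the planted run is maximal: break any accidental
      # extension of the motif at both ends
      first <- substr(s$motif, 1L, 1L); last <- substr(s$motif,
                                                       nchar(s$motif),
                                                       nchar(s$motif))
      write_at(s$chrom, p[1] - 1L, setdiff(c("A", "C", "G", "T"), last)[1])
      write_at(s$chrom, p[2] + 1L, setdiff(c("A", "C", "G", "T"), first)[1])
      ssr_truth <- rbind(ssr_truth, data.frame(
        chrom = paste0("chr", s$chrom), motif = s$motif,
        unit_size = nchar(s$motif), copies = s$copies,
        start = p[1], end = p[2], stringsAsFactors = FALSE))
    }
  }

  gene_models <- list()
  gene_truth <- NULL
  if (!is.null(spec$genes) && nrow(spec$genes)) {
    for (i in seq_len(nrow(spec$genes))) {
      g <- spec$genes[i, ]
      stopifnot(g$length %% 3L == 0L)
      ncod <- g$length %/% 3L - 2L
      sense <- setdiff(names(Biostrings::GENETIC_CODE),
                       c("TAA", "TAG", "TGA"))
      cds <- paste0("ATG", paste(sample(sense, ncod, replace = TRUE),
                                 collapse = ""), "TAA")
      k <- g$n_exons
      cuts <- if (k > 1L) sort(sample(seq(3L, g$length - 3L, by = 3L),
                                      k - 1L)) else integer(0)
      bounds <- cbind(c(1L, cuts + 1L), c(cuts, g$length))
      intron <- 100L
      span <- g$length + (k - 1L) * intron
      p <- alloc_interval(occupied, g$chrom, span,
                          spec$chrom_lengths[g$chrom])
      note(g$chrom, p[1], p[2])
      exons <- data.frame(start = integer(k), end = integer(k))
      cursor <- p[1]
      for (e in seq_len(k)) {
        chunk <- substr(cds, bounds[e, 1], bounds[e, 2])
        elen <- nchar(chunk)
        if (g$strand == "+") {
          write_at(g$chrom, cursor, chunk)
          exons$start[e] <- cursor; exons$end[e] <- cursor + elen - 1L
        } else {
          # transcription order exon e occupies the e-th block from the
          # RIGHT end of the span, holding the reverse complement
          pos <- p[2]
          blocks_before <- if (e > 1L)
            sum(bounds[1:(e - 1L), 2] - bounds[1:(e - 1L), 1] + 1L) +
              (e - 1L) * intron else 0L
          st <- pos - blocks_before - elen + 1L
          write_at(g$chrom, st, reverse_complement(chunk))
          exons$start[e] <- st; exons$end[e] <- st + elen - 1L
        }
        cursor <- cursor + elen + intron
      }
      gid <- paste0("gene", i)
      gene_models[[gid]] <- gene_model(gid, paste0("chr", g$chrom), exons,
                                       g$strand)
      gene_truth <- rbind(gene_truth, data.frame(
        gene_id = gid, chrom = paste0("chr", g$chrom), strand = g$strand,
        length = g$length, n_exons = k, span_start = p[1], span_end = p[2],
        cds = cds, stringsAsFactors = FALSE))
    }
  }

  chroms <- lapply(seq_len(nchrom),
                   function(i) chromosome(paste0("chr", i), seqs[i]))
  list(config = genome_config(chroms, name = "synthetic"),
       truth = list(repeats = repeat_truth, ssrs = ssr_truth,
                    genes = gene_models, gene_table = gene_truth))
}

#' Specification for long-read simulation
#'
#' @param n_reads Number of reads to draw; alternatively give `depth` and
#'   the read count is derived at simulation time as
#'   `round(depth * genome_length / length_mean)` using the
#'   mixture-weighted mean genome length.
#' @param depth Fold-coverage (used when `n_reads` is `NULL`).
#' @param length_mean,length_sd Read length distribution (bp).
#' @param error_rate Per-base error rate in `[0, 0.3]`; errors split
#'   substitution:insertion:deletion = 2:1:1, nanopore-like.
#' @param mixture Named proportions over configuration names (must sum
#'   to 1).
#' @param focus Optional named list (configuration name -> list(chrom,
#'   start, end)): reads from that configuration are drawn so that they
#'   fully cover the focus interval, making every read spanning-capable.
#' @param seed Integer seed.
#' @return List of class `mito_read_spec`.
#' @export
long_read_spec <- function(n_reads = 1000L, length_mean = 2000,
                           length_sd = 200, error_rate = 0.05,
                           mixture = c(ref = 1), focus = NULL, seed = 1L,
                           depth = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.3,
            abs(sum(mixture) - 1) < 1e-8)
  if (!is.null(depth)) n_reads <- NA_integer_   # resolved at simulation time
  structure(list(n_reads = as.integer(n_reads), depth = depth,
                 length_mean = length_mean,
                 length_sd = length_sd, error_rate = error_rate,
                 mixture = mixture, focus = focus, seed = as.integer(seed)),
            class = "mito_read_spec")
}

# Internal: apply substitution/insertion/deletion errors (2:1:1) to a read.
apply_read_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < error_rate)
  if (!length(hit)) return(seq)
  types <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                  prob = c(2, 1, 1))
  out <- as.list(v)
  for (t in seq_along(hit)) {
    i <- hit[t]
    out[[i]] <- switch(types[t],
      sub = sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L),
      ins = c(v[i], sample(c("A", "C", "G", "T"), 1L)),
      del = character(0))
  }
  paste(unlist(out), collapse = "")
}

#' Simulate long reads from a mixture of genome configurations
#'
#' Reads are drawn from circular templates (origin wrap permitted), on a
#' random strand, with substitution/insertion/deletion errors.  Per-read
#' truth records the source configuration and template interval.
#'
#' @param configs Named list of [genome_config()]s; names must cover the
#'   mixture keys.
#' @param spec A [long_read_spec()].
#' @return List: `reads` (data.frame `id, seq`) and `truth` (data.frame
#'   `id, config, chrom, start, length, strand`).
#' @export
simulate_long_reads <- function(configs, spec) {
  stopifnot(inherits(spec, "mito_read_spec"))
  if (inherits(configs, "mito_config")) configs <- list(configs)
  if (is.null(names(configs)) || !all(names(spec$mixture) %in% names(configs)))
    stop("mixture names must match provided configuration names")
  set.seed(spec$seed)
  n <- spec$n_reads
  if (is.na(n)) {
    glen <- sum(vapply(names(spec$mixture), function(nm)
      spec$mixture[[nm]] * config_length(configs[[nm]]), numeric(1)))
    n <- as.integer(round(spec$depth * glen / spec$length_mean))
  }
  src <- sample(names(spec$mixture), n, replace = TRUE, prob = spec$mixture)
  ids <- sprintf("read%05d", seq_len(n))
  seqs <- character(n)
  truth <- data.frame(id = ids, config = src, chrom = "", start = 0L,
                      length = 0L, strand = "+", stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    cfg <- configs[[src[r]]]
    lens <- vapply(cfg$chromosomes, `[[`, numeric(1), "length")
    foc <- spec$focus[[src[r]]]
    L <- max(50L, round(rnorm(1, spec$length_mean, spec$length_sd)))
    if (!is.null(foc)) {
      ch <- cfg$chromosomes[[foc$chrom]]
      span <- foc$end - foc$start + 1L
      L <- max(L, span)
      slack <- L - span
      st <- foc$start - sample.int(slack + 1L, 1L) + 1L
      st <- ((st - 1L) %% ch$length) + 1L
    } else {
      ch <- cfg$chromosomes[[sample(seq_along(lens), 1L, prob = lens)]]
      st <- sample.int(ch$length, 1L)
    }
    L <- min(L, ch$length)
    seqs[r] <- circ_substr(ch$sequence, st, L)
    truth$chrom[r] <- ch$id; truth$start[r] <- st
    truth$length[r] <- L
    truth$strand[r] <- sample(c("+", "-"), 1L)
  }
  flip <- truth$strand == "-"
  if (any(flip)) seqs[flip] <- reverse_complement(seqs[flip])
  if (spec$error_rate > 0)
    seqs <- vapply(seqs, apply_read_errors, character(1),
                   error_rate = spec$error_rate, USE.NAMES = FALSE)
  list(reads = data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE),
       truth = truth)
}

#' Specification of planted RNA editing and DNA SNPs
#'
#' @param sites data.frame `gene_id, cds_pos, extent`; each position must be
#'   a C on the coding strand.
#' @param snps data.frame `chrom, pos, alt, freq` of planted DNA variants
#'   (may be NULL).
#' @param rna_depth,dna_depth Mean per-site coverages (Poisson).
#' @param error_rate Per-base substitution error for the pileups.
#' @param seed Integer seed.
#' @return List of class `mito_editing_plan`.
#' @export
editing_plan <- function(sites, snps = NULL, rna_depth = 30, dna_depth = 30,
                         error_rate = 0, seed = 1L) {
  stopifnot(is.data.frame(sites), all(sites$extent >= 0 & sites$extent <= 1))
  structure(list(sites = sites, snps = snps, rna_depth = rna_depth,
                 dna_depth = dna_depth, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "mito_editing_plan")
}

# Internal: distribute `cov` reads carrying `base`, with substitution errors
# at rate e, into A/C/G/T counts.
pile_counts <- function(cov, base, e) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (cov == 0L) return(counts)
  err <- rbinom(1L, cov, e)
  counts[base] <- cov - err
  if (err > 0L) {
    alt <- sample(setdiff(names(counts), base), err, replace = TRUE)
    ta <- table(alt)
    counts[names(ta)] <- counts[names(ta)] + as.integer(ta)
  }
  counts
}

#' Simulate RNA and DNA pileups with planted editing and SNPs
#'
#' For every spliced-CDS position a Poisson coverage is drawn; at a planted
#' editing site each RNA read independently carries the edited base (T on
#' the coding strand, observed as A on the genome for minus-strand genes)
#' with probability equal to the planted extent.  DNA reads carry planted
#' SNP alleles at their planted frequency.  Substitution errors apply
#' uniformly.
#'
#' @param genome A [genome_config()].
#' @param genes List of [gene_model()]s.
#' @param plan An [editing_plan()].
#' @return List: `rna` and `dna` pileup data.frames
#'   (`chrom, pos, ref, A, C, G, T, source`) and `truth` (the plan's site
#'   table with genomic positions filled in).
#' @export
simulate_editing_reads <- function(genome, genes, plan) {
  stopifnot(inherits(plan, "mito_editing_plan"))
  set.seed(plan$seed)
  if (!is.null(names(genes))) gene_ids <- names(genes)
  else gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  rna <- dna <- list()
  truth <- NULL
  for (gi in seq_along(genes)) {
    g <- genes[[gi]]
    cds <- suppressWarnings(build_cds(g, genome))
    gpos <- cds_genomic_positions(g)
    cdsv <- strsplit(cds, "", fixed = TRUE)[[1]]
    planted <- plan$sites[plan$sites$gene_id == g$gene_id, , drop = FALSE]
    if (nrow(planted) && any(cdsv[planted$cds_pos] != "C"))
      stop("planted site at non-C coding-strand position in ", g$gene_id)
    extent_at <- setNames(planted$extent, planted$cds_pos)
    chseq <- genome$chromosomes[[g$chrom]]$sequence
    for (ci in seq_along(gpos)) {
      pos <- gpos[ci]
      ref <- substr(chseq, pos, pos)
      # RNA: transcript base observed on the genome plus strand
      plus_base <- ref
      cov <- rpois(1L, plan$rna_depth)
      ext <- extent_at[as.character(ci)]
      if (!is.na(ext) && length(ext)) {
        edited_plus <- if (g$strand == "+") "T" else "A"
        ne <- rbinom(1L, cov, ext)
        counts <- pile_counts(ne, edited_plus, plan$error_rate) +
          pile_counts(cov - ne, plus_base, plan$error_rate)
      } else {
        counts <- pile_counts(cov, plus_base, plan$error_rate)
      }
      rna[[length(rna) + 1L]] <- data.frame(
        chrom = g$chrom, pos = pos, ref = ref,
        A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
        T = counts[["T"]], source = "RNA", stringsAsFactors = FALSE)
      # DNA
      dcov <- rpois(1L, plan$dna_depth)
      snp <- if (!is.null(plan$snps))
        plan$snps[plan$snps$chrom == g$chrom & plan$snps$pos == pos, ,
                  drop = FALSE] else NULL
      if (!is.null(snp) && nrow(snp)) {
        na <- rbinom(1L, dcov, snp$freq[1])
        dcounts <- pile_counts(na, snp$alt[1], plan$error_rate) +
          pile_counts(dcov - na, ref, plan$error_rate)
      } else {
        dcounts <- pile_counts(dcov, ref, plan$error_rate)
      }
      dna[[length(dna) + 1L]] <- data.frame(
        chrom = g$chrom, pos = pos, ref = ref,
        A = dcounts[["A"]], C = dcounts[["C"]], G = dcounts[["G"]],
        T = dcounts[["T"]], source = "DNA", stringsAsFactors = FALSE)
    }
    if (nrow(planted))
      truth <- rbind(truth, cbind(planted,
                                  genomic_pos = gpos[planted$cds_pos],
                                  chrom = g$chrom))
  }
  list(rna = do.call(rbind, rna), dna = do.call(rbind, dna), truth = truth)
}
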