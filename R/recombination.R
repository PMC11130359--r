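## Repeat-mediated homologous recombination on circular chromosomes.
##
## Topology algebra for a crossover between two copies of a repeat:
##   direct repeat, one circle  -> split into two circles (one copy each)
##   direct repeat, two circles -> fusion into one circle (both copies kept)
##   inverted repeat, one circle -> inversion of the intervening segment
## Products are canonicalized to their lexicographically minimal rotation so
## enumeration is deterministic.

# Internal: accept either a repeat-table row or a mito_repeat object.
as_repeat <- function(repeat_pair) {
  if (inherits(repeat_pair, "mito_repeat")) repeat_pair
  else as_repeat_pair(repeat_pair)
}

#' Enumerate the recombination products mediated by one repeat pair
#'
#' @param config A [genome_config()] holding the chromosome(s) the repeat
#'   units lie on.
#' @param repeat_pair A `mito_repeat` (see [as_repeat_pair()]) or a one-row
#'   repeat table.
#' @param name Name for the product configuration.
#' @param canonical Canonicalize each circular product to its minimal
#'   rotation (default `TRUE`).  With `FALSE` the products keep the parent's
#'   coordinate frame, so the mediating repeat's unit coordinates remain
#'   valid in the product (useful for iterating events).
#' @return A list of class `mito_recomb_event`: `parent`, `repeat`,
#'   `event_class` (`"split"`, `"fusion"` or `"inversion"`) and `products`
#'   (a [genome_config()]).
#' @export
enumerate_recombinants <- function(config, repeat_pair, name = "recombinant",
                                   canonical = TRUE) {
  stopifnot(inherits(config, "mito_config"))
  rp <- as_repeat(repeat_pair)
  u1 <- rp$unit1; u2 <- rp$unit2
  c1 <- config$chromosomes[[u1$chrom]]
  c2 <- config$chromosomes[[u2$chrom]]
  if (is.null(c1) || is.null(c2))
    stop("repeat units reference chromosomes absent from the configuration")
  same <- identical(u1$chrom, u2$chrom)
  if (same && !(u1$end < u2$start || u2$end < u1$start))
    stop("repeat units overlap; crossover undefined")
  inverted <- rp$orientation == "inverted"
  if (inverted && !same)
    stop("inverted repeat spanning two circles: product topology unsupported")
  if (c1$topology != "circular" || c2$topology != "circular")
    stop("recombination enumeration requires circular chromosomes")

  prov <- list(parent = config$name, repeat_id = rp$id)
  canon <- if (canonical) canonical_rotation else identity
  if (same) {
    s <- c1$sequence
    a1 <- min(u1$start, u2$start); a2 <- max(u1$start, u2$start)
    b2 <- max(u1$end, u2$end)
    if (!inverted) {
      # split: cut at the two unit starts; each product keeps one copy
      p1 <- circ_substr(s, a1, a2 - a1)
      p2 <- circ_substr(s, a2, c1$length - (a2 - a1))
      prods <- list(
        canon(chromosome(paste0(name, "-1"), p1)),
        canon(chromosome(paste0(name, "-2"), p2)))
      ev <- "split"
    } else {
      # inversion: reverse-complement [start of unit1 .. end of unit2];
      # both repeat copies are preserved, the intervening segment flips
      seg <- substr(s, a1, b2)
      newseq <- paste0(substr(s, 1L, a1 - 1L), reverse_complement(seg),
                       substr(s, b2 + 1L, c1$length))
      prods <- list(canon(chromosome(paste0(name, "-1"), newseq)))
      ev <- "inversion"
    }
  } else {
    # fusion: rotate each circle to start at its repeat unit and concatenate
    r1 <- rotate(c1, u1$start - 1L)$sequence
    s2 <- if (inverted) stop("unreachable") else c2$sequence
    r2 <- rotate(c2, u2$start - 1L)$sequence
    prods <- list(canon(chromosome(paste0(name, "-1"), paste0(r1, r2))))
    ev <- "fusion"
  }
  structure(list(parent = config,
                 repeat_pair = rp,
                 event_class = ev,
                 products = genome_config(prods, name = name,
                                          provenance = prov)),
            class = "mito_recomb_event")
}

#' @export
print.mito_recomb_event <- function(x, ...) {
  cat(sprintf("<mito_recomb_event> %s via %s (%s)\n", x$event_class,
              x$repeat_pair$id, x$repeat_pair$orientation))
  print(x$products)
  invisible(x)
}

# Internal: flank upstream of position `pos` (excluded), length fl, on a
# chromosome; truncates on linear ends.
flank_up <- function(chrom, pos, fl) {
  n <- chrom$length
  if (chrom$topology == "circular") {
    circ_substr(chrom$sequence, ((pos - fl - 1L) %% n) + 1L, fl)
  } else {
    a <- max(1L, pos - fl)
    if (pos - 1L < 1L) "" else substr(chrom$sequence, a, pos - 1L)
  }
}

flank_down <- function(chrom, pos, fl) {
  n <- chrom$length
  if (chrom$topology == "circular") {
    circ_substr(chrom$sequence, (pos %% n) + 1L, fl)
  } else {
    if (pos + 1L > n) "" else substr(chrom$sequence, pos + 1L,
                                     min(n, pos + fl))
  }
}

#' Build the four junction references for a repeat pair
#'
#' Each junction is upstream flank + repeat unit + downstream flank.  `ref1`
#' and `ref2` splice the flanks as found in the input configuration; `alt1`
#' and `alt2` are the two crossover products (upstream of unit1 joined to
#' downstream of unit2 and vice versa, with strand correction for inverted
#' repeats).
#'
#' @param config A [genome_config()].
#' @param repeat_pair A `mito_repeat` or one-row repeat table.
#' @param flank_length Flank length in bp (default 500).
#' @return A list of class `mito_junction_model`: `repeat_pair`,
#'   `flank_length`, `junctions` (named character vector `ref1, ref2, alt1,
#'   alt2`), `flank_up_len`/`flank_down_len` (realized, possibly truncated),
#'   `unit_length` and `warnings`.
#' @export
build_junctions <- function(config, repeat_pair, flank_length = 500L) {
  stopifnot(flank_length >= 1L)
  rp <- as_repeat(repeat_pair)
  c1 <- config$chromosomes[[rp$unit1$chrom]]
  c2 <- config$chromosomes[[rp$unit2$chrom]]
  if (is.null(c1) || is.null(c2)) stop("repeat chromosomes not in config")
  unit_len <- interval_length(rp$unit1, c1$length)
  if (unit_len >= c1$length || interval_length(rp$unit2, c2$length) >= c2$length)
    stop("repeat unit as long as its chromosome")
  U <- extract_subsequence(c1, rp$unit1)

  up1 <- flank_up(c1, rp$unit1$start, flank_length)
  dn1 <- flank_down(c1, rp$unit1$end, flank_length)
  if (rp$orientation == "direct") {
    up2 <- flank_up(c2, rp$unit2$start, flank_length)
    dn2 <- flank_down(c2, rp$unit2$end, flank_length)
  } else {
    # orient unit2 like unit1: its upstream flank is the reverse complement
    # of the genomic sequence after the unit, and vice versa
    up2 <- reverse_complement(flank_down(c2, rp$unit2$end, flank_length))
    dn2 <- reverse_complement(flank_up(c2, rp$unit2$start, flank_length))
  }
  junc <- c(ref1 = paste0(up1, U, dn1),
            ref2 = paste0(up2, U, dn2),
            alt1 = paste0(up1, U, dn2),
            alt2 = paste0(up2, U, dn1))
  warn <- character(0)
  if (identical(rp$unit1$chrom, rp$unit2$chrom) &&
      (rp$unit2$start - rp$unit1$end == 1L ||
       rp$unit1$start - rp$unit2$end == 1L))
    warn <- c(warn, paste("adjacent repeat units (zero inter-repeat gap):",
                          "reference and crossover junctions share their",
                          "boundary context"))
  if (anyDuplicated(junc))
    warn <- c(warn, "junction sequences are not all distinct (homologous or adjacent flanks)")
  if (nchar(up1) < flank_length || nchar(up2) < flank_length ||
      nchar(dn1) < flank_length || nchar(dn2) < flank_length)
    warn <- c(warn, "flank truncated at linear chromosome end")
  for (w in warn) warning(w, call. = FALSE)
  structure(list(repeat_pair = rp, flank_length = as.integer(flank_length),
                 junctions = junc,
                 flank_up_len = c(ref1 = nchar(up1), ref2 = nchar(up2),
                                  alt1 = nchar(up1), alt2 = nchar(up2)),
                 flank_down_len = c(ref1 = nchar(dn1), ref2 = nchar(dn2),
                                    alt1 = nchar(dn2), alt2 = nchar(dn1)),
                 unit_length = nchar(U), warnings = warn),
            class = "mito_junction_model")
}

#' Write junction references as FASTA
#' @param jm A [build_junctions()] model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(jm, path) {
  x <- Biostrings::DNAStringSet(jm$junctions)
  names(x) <- paste0(jm$repeat_pair$id, "_", names(jm$junctions))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Classify long reads against a junction model
#'
#' A read supports a junction if it (or its reverse complement) aligns
#' across the full repeat unit plus at least `min_anchor` bases of both
#' flanks, with overall divergence (edit distance / read length) at most
#' `max_divergence`.  A read matching several junctions goes to the
#' best-scoring one; ties within the same class (both reference or both
#' crossover junctions) count once for that class, ties across classes are
#' unassigned.
#'
#' @param reads Character vector of read sequences (or a data.frame with a
#'   `seq` column, as produced by [simulate_long_reads()]).
#' @param jm A [build_junctions()] model.
#' @param min_anchor Minimum flank anchor in bp (default 100).
#' @param max_divergence Maximum edit-distance fraction (default 0.15,
#'   nanopore-like).
#' @return A list of class `mito_read_support`: `per_junction` counts,
#'   `major_count` (ref1+ref2), `minor_count` (alt1+alt2), `minor_percent`,
#'   `unassigned`, and per-read `assignment`.
#' @export
classify_spanning_reads <- function(reads, jm, min_anchor = 100L,
                                    max_divergence = 0.15) {
  if (is.data.frame(reads)) reads <- reads$seq
  stopifnot(inherits(jm, "mito_junction_model"), min_anchor >= 1L,
            max_divergence >= 0, max_divergence < 1)
  if (!length(jm$junctions)) stop("empty junction model")
  labs <- names(jm$junctions)
  # required covered interval within each junction sequence
  lo <- jm$flank_up_len - min_anchor + 1L
  hi <- jm$flank_up_len + jm$unit_length + min_anchor
  usable <- jm$flank_up_len >= min_anchor & jm$flank_down_len >= min_anchor
  assignment <- character(length(reads))
  counts <- setNames(integer(length(labs)), labs)
  unassigned <- 0L
  if (!any(usable)) stop("no junction provides ", min_anchor, " bp anchors")
  juncs <- jm$junctions[usable]
  labs_u <- labs[usable]
  lo <- lo[usable]; hi <- hi[usable]
  rc_reads <- reverse_complement(reads)
  maxed <- as.integer(floor(max_divergence * nchar(reads)))
  cost <- .classify_read_batch(reads, rc_reads, unname(juncs),
                               as.integer(lo), as.integer(hi), maxed)
  for (r in seq_along(reads)) {
    best <- cost[r, ]
    if (all(is.na(best))) { assignment[r] <- "unassigned"; unassigned <- unassigned + 1L; next }
    b <- min(best, na.rm = TRUE)
    winners <- labs_u[!is.na(best) & best == b]
    cls <- unique(substr(winners, 1, 3))
    if (length(winners) == 1L) {
      assignment[r] <- winners
      counts[winners] <- counts[winners] + 1L
    } else if (length(cls) == 1L) {
      # read consistent with both junctions of one configuration: count once
      assignment[r] <- winners[1]
      counts[winners[1]] <- counts[winners[1]] + 1L
    } else {
      assignment[r] <- "unassigned"
      unassigned <- unassigned + 1L
    }
  }
  major <- sum(counts[grepl("^ref", names(counts))])
  minor <- sum(counts[grepl("^alt", names(counts))])
  structure(list(per_junction = counts,
                 major_count = major, minor_count = minor,
                 minor_percent = if (major + minor > 0)
                   minor_fraction(major, minor) else NA_real_,
                 unassigned = unassigned,
                 assignment = assignment),
            class = "mito_read_support")
}

#' @export
print.mito_read_support <- function(x, ...) {
  cat("<mito_read_support>\n")
  print(x$per_junction)
  cat(sprintf("major %d, minor %d, minor%% %s, unassigned %d\n",
              x$major_count, x$minor_count,
              ifelse(is.na(x$minor_percent), "NA",
                     sprintf("%.2f", x$minor_percent)), x$unassigned))
  invisible(x)
}

#' Percentage of the minor configuration
#'
#' `100 * minor / (major + minor)`, rounded to two decimals.
#'
#' @param major,minor Non-negative spanning-read counts.
#' @return Percentage (numeric scalar).
#' @examples
#' minor_fraction(17, 7)   # 29.17
#' minor_fraction(64, 54)  # 45.76
#' @export
minor_fraction <- function(major, minor) {
  stopifnot(major >= 0, minor >= 0)
  if (major + minor == 0) stop("both counts are zero")
  round(100 * minor / (major + minor), 2)
}

#' Screen repeat pairs for long-read recombination support
#'
#' Runs [build_junctions()] + [classify_spanning_reads()] for every repeat
#' pair and flags a pair as recombination-supported when at least
#' `min_minor_reads` reads back a crossover junction.
#'
#' @param config A [genome_config()].
#' @param repeats A [find_dispersed_repeats()] table (or list of
#'   `mito_repeat`).
#' @param reads Character vector of long reads (or data.frame with `seq`).
#' @param flank_length,min_anchor,max_divergence See [build_junctions()] and
#'   [classify_spanning_reads()].
#' @param min_minor_reads Support threshold (default 3).
#' @return A list: `table` (one row per repeat: id, orientation, major,
#'   minor, minor_percent, unassigned, supported) and `supports` (named list
#'   of `mito_read_support`).
#' @export
recombination_screen <- function(config, repeats, reads,
                                 flank_length = 500L, min_anchor = 100L,
                                 max_divergence = 0.15,
                                 min_minor_reads = 3L) {
  if (is.data.frame(repeats))
    repeats <- lapply(seq_len(nrow(repeats)),
                      function(i) as_repeat_pair(repeats[i, , drop = FALSE]))
  supports <- list()
  rows <- list()
  for (rp in repeats) {
    jm <- build_junctions(config, rp, flank_length)
    rs <- if (length(reads)) classify_spanning_reads(reads, jm, min_anchor,
                                                     max_divergence)
          else structure(list(per_junction = setNames(integer(4),
                                                      names(jm$junctions)),
                              major_count = 0L, minor_count = 0L,
                              minor_percent = NA_real_, unassigned = 0L,
                              assignment = character(0)),
                         class = "mito_read_support")
    supports[[rp$id]] <- rs
    rows[[length(rows) + 1L]] <- data.frame(
      repeat_id = rp$id, orientation = rp$orientation,
      major = rs$major_count, minor = rs$minor_count,
      minor_percent = rs$minor_percent, unassigned = rs$unassigned,
      supported = rs$minor_count >= min_minor_reads,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(repeat_id = character(0), orientation = character(0),
               major = integer(0), minor = integer(0),
               minor_percent = numeric(0), unassigned = integer(0),
               supported = logical(0))
  list(table = tab, supports = supports)
}

#' Write a read-support table as TSV
#' @param screen A [recombination_screen()] result (or its `table`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_support_tsv <- function(screen, path) {
  tab <- if (is.data.frame(screen)) screen else screen$table
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
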