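## Dispersed repeat discovery: exact k-mer seeding, same-diagonal merging of
## exact runs, then mismatch-bridging chaining.  No E-value model: filtering
## is by minimum length and percent identity, which is what downstream
## recombination screening actually conditions on.

# Internal: maximal exact diagonal runs between s1 and s2 (both plain
# strings), as a data.frame(start1, start2, len).  `self` excludes the main
# diagonal and mirror duplicates of a self-comparison.
exact_diagonal_runs <- function(s1, s2, k, self = FALSE, max_occ = 512L) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (n1 < k || n2 < k) return(data.frame(start1 = integer(0),
                                          start2 = integer(0),
                                          len = integer(0)))
  k1 <- substring(s1, 1:(n1 - k + 1L), k:n1)
  k2 <- substring(s2, 1:(n2 - k + 1L), k:n2)
  common <- intersect(unique(k1), unique(k2))
  if (!length(common)) return(data.frame(start1 = integer(0),
                                         start2 = integer(0),
                                         len = integer(0)))
  p1 <- split(seq_along(k1), factor(k1, levels = common))
  p2 <- split(seq_along(k2), factor(k2, levels = common))
  i <- j <- vector("list", length(common))
  for (t in seq_along(common)) {
    a <- p1[[t]]; b <- p2[[t]]
    if (length(a) > max_occ || length(b) > max_occ) next  # low-complexity guard
    g <- expand.grid(a = a, b = b)
    i[[t]] <- g$a; j[[t]] <- g$b
  }
  i <- unlist(i); j <- unlist(j)
  if (is.null(i) || !length(i)) return(data.frame(start1 = integer(0),
                                                  start2 = integer(0),
                                                  len = integer(0)))
  if (self) {
    keep <- i < j   # one triangle; removes self-hit and mirrors
    i <- i[keep]; j <- j[keep]
  }
  if (!length(i)) return(data.frame(start1 = integer(0),
                                    start2 = integer(0), len = integer(0)))
  d <- j - i
  ord <- order(d, i)
  i <- i[ord]; j <- j[ord]; d <- d[ord]
  newrun <- c(TRUE, d[-1] != d[-length(d)] | i[-1] != i[-length(i)] + 1L)
  run <- cumsum(newrun)
  st1 <- i[newrun]
  st2 <- j[newrun]
  cnt <- tabulate(run)
  data.frame(start1 = st1, start2 = st2, len = cnt + k - 1L)
}

# Internal: greedy same-diagonal chaining of exact runs into ungapped local
# alignments whose identity stays >= min_identity.  Runs must share diagonal.
chain_diagonal_runs <- function(runs, min_identity) {
  if (!nrow(runs)) return(cbind(runs, mism = integer(0)))
  d <- runs$start2 - runs$start1
  out <- vector("list", 0L)
  for (dg in unique(d)) {
    r <- runs[d == dg, , drop = FALSE]
    r <- r[order(r$start1), , drop = FALSE]
    cs1 <- r$start1[1]; cs2 <- r$start2[1]; clen <- r$len[1]; cmm <- 0L
    flush <- function() data.frame(start1 = cs1, start2 = cs2,
                                   len = clen, mism = cmm)
    if (nrow(r) > 1) for (t in 2:nrow(r)) {
      gap <- r$start1[t] - (cs1 + clen)       # mismatching bases between runs
      newlen <- r$start1[t] + r$len[t] - cs1
      newmm <- cmm + gap
      if (gap >= 0 && 100 * (newlen - newmm) / newlen >= min_identity) {
        clen <- newlen; cmm <- newmm
      } else {
        out[[length(out) + 1L]] <- flush()
        cs1 <- r$start1[t]; cs2 <- r$start2[t]; clen <- r$len[t]; cmm <- 0L
      }
    }
    out[[length(out) + 1L]] <- flush()
  }
  do.call(rbind, out)
}

# Internal: alignments between two sequences in the given orientation.
# For orientation "inverted", s2 is compared as its reverse complement and
# coordinates are mapped back to the plus strand of s2.
pair_alignments <- function(s1, s2, orientation, min_length, min_identity,
                            seed_size, self_same = FALSE) {
  t2 <- if (orientation == "inverted") reverse_complement(s2) else s2
  runs <- exact_diagonal_runs(s1, t2, seed_size,
                              self = self_same && orientation == "direct")
  ali <- chain_diagonal_runs(runs, min_identity)
  if (!nrow(ali)) return(NULL)
  ali <- ali[ali$len >= min_length, , drop = FALSE]
  if (!nrow(ali)) return(NULL)
  n2 <- nchar(s2)
  if (orientation == "inverted") {
    e2 <- n2 - ali$start2 + 1L            # plus-strand end of unit2
    b2 <- e2 - ali$len + 1L               # plus-strand start of unit2
    ali$u2_start <- b2; ali$u2_end <- e2
  } else {
    ali$u2_start <- ali$start2
    ali$u2_end <- ali$start2 + ali$len - 1L
  }
  ali$u1_start <- ali$start1
  ali$u1_end <- ali$start1 + ali$len - 1L
  if (self_same) {
    if (orientation == "inverted") {
      # self inverted comparison reports each pair twice (and palindromic
      # self-hits once); canonicalize to u1 before u2 and drop self-overlaps
      keep <- ali$u1_start < ali$u2_start
      ali <- ali[keep, , drop = FALSE]
    }
    if (nrow(ali)) {
      # drop pairs whose units overlap each other on the same chromosome
      keep <- ali$u1_end < ali$u2_start | ali$u2_end < ali$u1_start
      ali <- ali[keep, , drop = FALSE]
    }
  }
  if (!nrow(ali)) return(NULL)
  ali
}

#' Find dispersed repeat pairs (direct and inverted)
#'
#' Scans all chromosome pairs of a configuration (including each chromosome
#' against itself) for locally maximal ungapped alignments between two
#' distinct loci.  Orientation is `direct` when the two units align on the
#' same strand and `inverted` otherwise.  Each unordered pair of loci is
#' reported once; ids `R1, R2, ...` are assigned by descending alignment
#' length, then coordinates.
#'
#' Defaults (`min_length = 1000`, `min_identity = 99`) target the long,
#' near-identical repeats that mediate observable recombination; shorter
#' repeats can be recovered by lowering the thresholds.
#'
#' @param config A [genome_config()].
#' @param min_length Minimum alignment length in bp.
#' @param min_identity Minimum percent identity (0-100].
#' @param seed_size Exact k-mer seed length (default 13).
#' @return A data.frame with one row per repeat pair: `id`,
#'   `identity_percent`, `alignment_length`, `mismatches`, `gap_openings`,
#'   `unit1_chrom`, `unit1_start`, `unit1_end`, `unit2_chrom`, `unit2_start`,
#'   `unit2_end`, `orientation`, `score`.  For inverted pairs unit2 is the
#'   minus-strand unit; `unit2_start > unit2_end` follows the plus-strand
#'   coordinate convention of published repeat tables.
#' @export
find_dispersed_repeats <- function(config, min_length = 1000,
                                   min_identity = 99, seed_size = 13) {
  stopifnot(inherits(config, "mito_config"),
            min_length >= seed_size, min_identity > 0, min_identity <= 100)
  chroms <- config$chromosomes
  if (!length(chroms)) stop("empty configuration")
  rows <- list()
  ids <- names(chroms)
  for (a in seq_along(ids)) for (b in a:length(ids)) {
    s1 <- chroms[[a]]$sequence; s2 <- chroms[[b]]$sequence
    for (orient in c("direct", "inverted")) {
      ali <- pair_alignments(s1, s2, orient, min_length, min_identity,
                             seed_size, self_same = a == b)
      if (is.null(ali)) next
      rows[[length(rows) + 1L]] <- data.frame(
        identity_percent = round(100 * (ali$len - ali$mism) / ali$len, 3),
        alignment_length = ali$len,
        mismatches = ali$mism,
        gap_openings = 0L,
        unit1_chrom = ids[a], unit1_start = ali$u1_start,
        unit1_end = ali$u1_end,
        unit2_chrom = ids[b],
        unit2_start = if (orient == "inverted") ali$u2_end else ali$u2_start,
        unit2_end   = if (orient == "inverted") ali$u2_start else ali$u2_end,
        orientation = orient,
        score = 2L * (ali$len - ali$mism) - 3L * ali$mism,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(id = character(0), identity_percent = numeric(0),
                      alignment_length = integer(0), mismatches = integer(0),
                      gap_openings = integer(0), unit1_chrom = character(0),
                      unit1_start = integer(0), unit1_end = integer(0),
                      unit2_chrom = character(0), unit2_start = integer(0),
                      unit2_end = integer(0), orientation = character(0),
                      score = integer(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$alignment_length, out$unit1_chrom, out$unit1_start,
               out$unit2_chrom, out$unit2_start)
  out <- out[ord, , drop = FALSE]
  out <- cbind(id = paste0("R", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Convert one repeat-table row into a repeat-pair object
#'
#' @param row One row of a [find_dispersed_repeats()] table.
#' @return A list of class `mito_repeat` with `unit1`/`unit2` intervals
#'   (always stored start <= end; inverted unit2 carries strand `"-"`).
#' @export
as_repeat_pair <- function(row) {
  stopifnot(is.data.frame(row), nrow(row) == 1L)
  inv <- row$orientation == "inverted"
  u2s <- min(row$unit2_start, row$unit2_end)
  u2e <- max(row$unit2_start, row$unit2_end)
  structure(list(
    id = row$id,
    unit1 = interval(row$unit1_chrom, row$unit1_start, row$unit1_end, "+"),
    unit2 = interval(row$unit2_chrom, u2s, u2e, if (inv) "-" else "+"),
    orientation = row$orientation,
    alignment_length = row$alignment_length,
    identity_percent = row$identity_percent),
    class = "mito_repeat")
}

#' Write a dispersed-repeat table as TSV
#' @param repeats A [find_dispersed_repeats()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_tsv <- function(repeats, path) {
  write.table(repeats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## --- SSRs -------------------------------------------------------------

default_ssr_minima <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L,
                        `6` = 5L)

# Internal: is motif primitive (not a whole-number power of a shorter motif)?
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (strrep(substr(motif, 1L, d), u %/% d) == motif) return(FALSE)
  }
  TRUE
}

# Internal: SSR scan of a single linear string; returns 1-based coordinates.
# A period-u tandem region is a maximal run of s[i] == s[i+u]; a run whose
# leading motif is non-primitive is left to the smaller period that
# generates it (Fine-Wilf guarantees it is found there).
scan_ssrs_linear <- function(s, min_copies) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  res <- list()
  for (u in 1:6) {
    if (n <= u) break
    eq <- v[seq_len(n - u)] == v[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (t in which(r$values)) {
      a <- starts[t]
      reg_len <- r$lengths[t] + u          # region [a, ends[t] + u]
      copies <- reg_len %/% u
      if (copies < min_copies[[as.character(u)]]) next
      motif <- substr(s, a, a + u - 1L)
      if (!is_primitive_motif(motif)) next
      res[[length(res) + 1L]] <- data.frame(
        motif = motif, unit_size = u, copies = copies,
        start = a, end = a + copies * u - 1L,
        total_length = copies * u, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(data.frame(motif = character(0),
                                      unit_size = integer(0),
                                      copies = integer(0), start = integer(0),
                                      end = integer(0),
                                      total_length = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$unit_size), , drop = FALSE]
}

# Internal: drop overlapping SSR calls, keeping the longer run
# (ties: smaller unit size, then leftmost).
drop_overlaps <- function(df) {
  if (nrow(df) < 2L) return(df)
  df <- df[order(-df$total_length, df$unit_size, df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (t in seq_len(nrow(df))[-1]) {
    prior <- which(keep[seq_len(t - 1L)])
    if (any(df$start[t] <= df$end[prior] & df$end[t] >= df$start[prior]))
      keep[t] <- FALSE
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

#' Find simple sequence repeats (microsatellites)
#'
#' Maximal perfect tandem runs of a 1-6 bp motif meeting a MISA-style
#' class-specific minimum copy number (default `1-10 2-6 3-5 4-5 5-5 6-5`).
#' A run is reported once, at the primitive period of its motif, and no two
#' reported SSRs overlap.  Circular chromosomes are scanned with an overhang
#' across the origin so origin-spanning runs are found; their `end`
#' coordinate wraps.
#'
#' @param config A [genome_config()].
#' @param min_copies Named vector/list mapping unit size `"1"`..`"6"` to the
#'   minimum copy number.
#' @return data.frame: `chrom, motif, unit_size, copies, start, end,
#'   total_length`.
#' @export
find_ssrs <- function(config, min_copies = default_ssr_minima) {
  stopifnot(inherits(config, "mito_config"))
  min_copies <- as.list(min_copies)
  stopifnot(all(as.character(1:6) %in% names(min_copies)))
  out <- list()
  for (ch in config$chromosomes) {
    s <- ch$sequence
    n <- nchar(s)
    over <- if (ch$topology == "circular") min(n, 300L) else 0L
    ext <- paste0(s, substr(s, 1L, over))
    df <- scan_ssrs_linear(ext, min_copies)
    if (nrow(df)) {
      df <- df[df$start <= n, , drop = FALSE]       # calls starting in-genome
      # a full-circle homopolymer-ish run can double-report via the overhang
      df$end <- ifelse(df$end > n, df$end - n, df$end)
      df <- drop_overlaps_wrapped(df, n)
      if (nrow(df))
        out[[length(out) + 1L]] <- cbind(chrom = ch$id, df,
                                         stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(data.frame(chrom = character(0),
                                      motif = character(0),
                                      unit_size = integer(0),
                                      copies = integer(0), start = integer(0),
                                      end = integer(0),
                                      total_length = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Internal: overlap removal aware of origin-wrapping calls on an n-bp circle.
drop_overlaps_wrapped <- function(df, n) {
  if (nrow(df) < 2L) return(df)
  covered <- function(row) {
    if (row$start <= row$end) row$start:row$end
    else c(row$start:n, 1:row$end)
  }
  df <- df[order(-df$total_length, df$unit_size, df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  occ <- logical(n)
  for (t in seq_len(nrow(df))) {
    pos <- covered(df[t, ])
    if (any(occ[pos])) keep[t] <- FALSE else occ[pos] <- TRUE
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

#' Summarize SSRs by unit-size class
#'
#' Counts per chromosome per unit-size class (mono- through hexanucleotide)
#' and the proportion of each class over all records, as a percentage rounded
#' to one decimal.
#'
#' @param records A [find_ssrs()]-style data.frame (needs `chrom`,
#'   `unit_size`).
#' @return List with `counts` (chromosomes x classes matrix), `totals`
#'   (per-chromosome totals) and `proportions` (named percentage per class;
#'   empty when there are no records).
#' @export
summarize_ssrs <- function(records) {
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  if (is.null(records) || !nrow(records)) {
    counts <- matrix(0L, nrow = 0, ncol = 6,
                     dimnames = list(NULL, classes))
    return(list(counts = counts, totals = integer(0),
                proportions = numeric(0)))
  }
  tab <- table(factor(records$chrom, levels = unique(records$chrom)),
               factor(records$unit_size, levels = 1:6))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), classes))
  totals <- rowSums(counts)
  class_tot <- colSums(counts)
  proportions <- round(100 * class_tot / sum(class_tot), 1)
  names(proportions) <- classes
  list(counts = counts, totals = totals, proportions = proportions)
}

## --- Simple tandem repeats -------------------------------------------

#' Find tandem repeats with a simplified period scan
#'
#' Reports maximal regions where a period-`p` pattern repeats at least twice
#' with a bounded mismatch fraction and a minimum total length.  This is a
#' deliberately simple detector (self-comparison at lag `p`), not a
#' reimplementation of the Tandem Repeats Finder scoring model.
#'
#' @param chrom A [chromosome()].
#' @param min_period,max_period Period range in bp (defaults 7 and 50;
#'   microsatellite-range periods 1-6 belong to [find_ssrs()]).
#' @param min_total Minimum region length in bp (default 14, i.e. two copies
#'   of the smallest period).
#' @param max_mismatch_fraction Maximum fraction of mismatching positions in
#'   the lag-`p` self-comparison of the region (default 0.2).
#' @return data.frame: `chrom, period, copy_number, consensus, start, end`.
#' @export
find_tandem_repeats_simple <- function(chrom, min_period = 7L,
                                       max_period = 50L, min_total = 14L,
                                       max_mismatch_fraction = 0.2) {
  stopifnot(inherits(chrom, "mito_chrom"),
            min_period >= 2L, min_period <= max_period)
  s <- chrom$sequence
  n <- nchar(s)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  res <- list()
  for (p in min_period:min(max_period, n %/% 2L)) {
    eq <- v[seq_len(n - p)] == v[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # merge TRUE runs separated by short FALSE runs while the overall
    # mismatch fraction stays within bounds
    idx <- which(r$values)
    if (!length(idx)) next
    t <- 1L
    while (t <= length(idx)) {
      a <- idx[t]
      b <- a
      mm <- 0L
      while (b + 2L <= length(r$values) && r$values[b + 1L] == FALSE &&
             t + 1L <= length(idx) && idx[t + 1L] == b + 2L) {
        cand_mm <- mm + r$lengths[b + 1L]
        cand_len <- ends[b + 2L] - starts[a] + 1L
        if (cand_mm / cand_len <= max_mismatch_fraction) {
          mm <- cand_mm; b <- b + 2L; t <- t + 1L
        } else break
      }
      reg_start <- starts[a]
      reg_end <- ends[b] + p          # region covers the lagged copy too
      reg_len <- reg_end - reg_start + 1L
      if (reg_len >= max(min_total, 2L * p)) {
        cons <- substr(s, reg_start, reg_start + p - 1L)
        res[[length(res) + 1L]] <- data.frame(
          chrom = chrom$id, period = p,
          copy_number = round(reg_len / p, 2),
          consensus = cons, start = reg_start, end = reg_end,
          stringsAsFactors = FALSE)
      }
      t <- t + 1L
    }
  }
  if (!length(res)) return(data.frame(chrom = character(0),
                                      period = integer(0),
                                      copy_number = numeric(0),
                                      consensus = character(0),
                                      start = integer(0), end = integer(0)))
  out <- do.call(rbind, res)
  # prefer the smallest period covering a region: drop calls whose interval
  # is contained in a call with smaller period
  out <- out[order(out$period, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  if (nrow(out) > 1L) for (t in 2:nrow(out)) {
    prior <- which(keep[seq_len(t - 1L)])
    contained <- out$start[t] >= out$start[prior] &
      out$end[t] <= out$end[prior] & out$period[prior] <= out$period[t]
    if (any(contained)) keep[t] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
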