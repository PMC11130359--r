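# Shared fixture builders and independent brute-force oracles.  Oracles use
# exhaustive offset/position scans, deliberately different algorithms from
# the package's k-mer seeding and rle-based detectors.

rnd_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A one-circle world X-R-Y-R-Z with a planted direct repeat, its split
# products rotated so the repeat copy sits at [1001, 1300], and focus
# intervals (repeat +/- 100 bp anchors) for spanning-read simulation.
make_direct_repeat_world <- function(seed, repeat_len = 300L) {
  set.seed(seed)
  X <- rnd_dna(1500); R <- rnd_dna(repeat_len)
  Y <- rnd_dna(1200); Z <- rnd_dna(1500)
  ref <- genome_config(chromosome("c1", paste0(X, R, Y, R, Z)), name = "ref")
  u1s <- 1501L; u1e <- u1s + repeat_len - 1L
  u2s <- u1e + 1200L + 1L; u2e <- u2s + repeat_len - 1L
  rp <- structure(list(id = "R1",
                       unit1 = interval("c1", u1s, u1e),
                       unit2 = interval("c1", u2s, u2e),
                       orientation = "direct",
                       alignment_length = repeat_len,
                       identity_percent = 100),
                  class = "mito_repeat")
  ev <- enumerate_recombinants(ref, rp, canonical = FALSE, name = "mic")
  prods <- lapply(ev$products$chromosomes,
                  function(ch) rotate(ch, ch$length - 1000L))
  # split product 1 is R+Y (alt2 junction), product 2 is R+Z+X (alt1)
  list(ref = ref, rp = rp, parts = list(X = X, R = R, Y = Y, Z = Z),
       alt1 = genome_config(chromosome("a1", prods[[2]]$sequence),
                            name = "alt1"),
       alt2 = genome_config(chromosome("a2", prods[[1]]$sequence),
                            name = "alt2"),
       focus = list(ref  = list(chrom = "c1", start = u1s - 100L,
                                end = u1e + 100L),
                    alt1 = list(chrom = "a1", start = 901L, end = 1300L + 100L),
                    alt2 = list(chrom = "a2", start = 901L, end = 1300L + 100L)))
}

run_mixture_seed <- function(seed, minor = 0.3, err = 0.1, n = 1000L) {
  w <- make_direct_repeat_world(seed)
  spec <- long_read_spec(n_reads = n, length_mean = 560, length_sd = 20,
                         error_rate = err,
                         mixture = c(ref = 1 - minor, alt1 = minor / 2,
                                     alt2 = minor / 2),
                         focus = w$focus, seed = seed + 1000L)
  rd <- simulate_long_reads(list(ref = w$ref, alt1 = w$alt1, alt2 = w$alt2),
                            spec)
  jm <- build_junctions(w$ref, w$rp, flank_length = 200L)
  classify_spanning_reads(rd$reads$seq, jm, min_anchor = 100L,
                          max_divergence = 0.15)
}

# --- Oracle: maximal exact repeated pairs by exhaustive diagonal scan ----

oracle_runs_between <- function(s1, s2, min_len) {
  v1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  v2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  n1 <- length(v1); n2 <- length(v2)
  out <- NULL
  for (d in (-(n1 - 1L)):(n2 - 1L)) {
    i0 <- max(1L, 1L - d); i1 <- min(n1, n2 - d)
    if (i1 - i0 + 1L < min_len) next
    idx <- i0:i1
    eq <- v1[idx] == v2[idx + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (t in which(r$values & r$lengths >= min_len)) {
      a <- idx[starts[t]]
      out <- rbind(out, data.frame(start1 = a, start2 = a + d,
                                   len = r$lengths[t]))
    }
  }
  out
}

# All maximal exact repeat pairs (>= min_len, both orientations) in a
# configuration; mirrors the reporting contract (each unordered pair once,
# no self-overlapping unit pairs on one chromosome).
oracle_exact_repeats <- function(config, min_len) {
  ids <- names(config$chromosomes)
  out <- NULL
  for (a in seq_along(ids)) for (b in a:length(ids)) {
    s1 <- config$chromosomes[[a]]$sequence
    s2 <- config$chromosomes[[b]]$sequence
    n2 <- nchar(s2)
    dir <- oracle_runs_between(s1, s2, min_len)
    if (!is.null(dir)) {
      if (a == b) {
        dir <- dir[dir$start1 < dir$start2, , drop = FALSE]
        dir <- dir[dir$start1 + dir$len - 1L < dir$start2, , drop = FALSE]
      }
      if (nrow(dir)) out <- rbind(out, data.frame(
        unit1_chrom = ids[a], u1s = dir$start1, u1e = dir$start1 + dir$len - 1L,
        unit2_chrom = ids[b], u2s = dir$start2, u2e = dir$start2 + dir$len - 1L,
        len = dir$len, orientation = "direct"))
    }
    inv <- oracle_runs_between(s1, reverse_complement(s2), min_len)
    if (!is.null(inv)) {
      u2e <- n2 - inv$start2 + 1L
      u2s <- u2e - inv$len + 1L
      df <- data.frame(unit1_chrom = ids[a], u1s = inv$start1,
                       u1e = inv$start1 + inv$len - 1L,
                       unit2_chrom = ids[b], u2s = u2s, u2e = u2e,
                       len = inv$len, orientation = "inverted")
      if (a == b) {
        df <- df[df$u1s < df$u2s, , drop = FALSE]
        df <- df[df$u1e < df$u2s | df$u2e < df$u1s, , drop = FALSE]
      }
      if (nrow(df)) out <- rbind(out, df)
    }
  }
  out
}

repeat_key <- function(df) {
  if (is.null(df) || !nrow(df)) return(character(0))
  sort(paste(df$unit1_chrom, df$u1s, df$u1e, df$unit2_chrom,
             pmin(df$u2s, df$u2e), pmax(df$u2s, df$u2e), df$orientation))
}

scan_key <- function(tab) {
  if (!nrow(tab)) return(character(0))
  sort(paste(tab$unit1_chrom, tab$unit1_start, tab$unit1_end,
             tab$unit2_chrom, pmin(tab$unit2_start, tab$unit2_end),
             pmax(tab$unit2_start, tab$unit2_end), tab$orientation))
}

# --- Oracle: SSRs by per-position motif extension -----------------------

oracle_ssrs <- function(s, minima = c(`1` = 10, `2` = 6, `3` = 5, `4` = 5,
                                      `5` = 5, `6` = 5)) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  is_prim <- function(m) {
    u <- nchar(m)
    if (u == 1L) return(TRUE)
    !any(vapply(seq_len(u - 1L), function(d)
      u %% d == 0L && strrep(substr(m, 1L, d), u %/% d) == m, logical(1)))
  }
  out <- NULL
  for (u in 1:6) for (i in seq_len(n - u)) {
    # run start: the period-u lag match must fail just before i
    if (i > 1L && v[i - 1L] == v[i - 1L + u]) next
    copies <- 1L
    while (i + copies * u + u - 1L <= n &&
           all(v[i:(i + u - 1L)] == v[(i + copies * u):(i + copies * u + u - 1L)]))
      copies <- copies + 1L
    if (copies < minima[[as.character(u)]]) next
    m <- paste(v[i:(i + u - 1L)], collapse = "")
    if (!is_prim(m)) next
    out <- rbind(out, data.frame(motif = m, unit_size = u, copies = copies,
                                 start = i, end = i + copies * u - 1L))
  }
  out
}

ssr_key <- function(df) {
  if (is.null(df) || !nrow(df)) return(character(0))
  sort(paste(df$motif, df$copies, df$start, df$end))
}

# --- Oracle: exact tandem regions (mismatch fraction 0) ------------------

oracle_exact_tandems <- function(s, min_period, max_period, min_total) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(v)
  out <- NULL
  for (p in min_period:min(max_period, n %/% 2L)) {
    eq <- v[seq_len(n - p)] == v[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (t in which(r$values)) {
      reg_len <- r$lengths[t] + p
      if (reg_len >= max(min_total, 2L * p))
        out <- rbind(out, data.frame(period = p, start = starts[t],
                                     end = ends[t] + p))
    }
  }
  out
}
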