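base_count <- function(x) {
  s <- paste(unlist(x), collapse = "")
  v <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  as.integer(v)
}
config_seqs <- function(cfg) vapply(cfg$chromosomes, `[[`, "", "sequence")

test_that("direct repeat on one circle splits into two conserving circles", {
  w <- make_direct_repeat_world(100)
  ev <- enumerate_recombinants(w$ref, w$rp)
  expect_equal(ev$event_class, "split")
  expect_equal(length(ev$products$chromosomes), 2)
  expect_equal(config_length(ev$products), config_length(w$ref))
  expect_identical(base_count(config_seqs(ev$products)),
                   base_count(config_seqs(w$ref)))
  # each product retains exactly one repeat copy (circular search: extend
  # the sequence by one pattern length minus one across the origin)
  for (p in ev$products$chromosomes) {
    ext <- paste0(p$sequence, substr(p$sequence, 1, nchar(w$parts$R) - 1))
    hits <- gregexpr(w$parts$R, ext, fixed = TRUE)[[1]]
    expect_equal(sum(hits > 0), 1)
  }
})

test_that("direct repeat across two circles fuses them; split reverts", {
  set.seed(101)
  R <- rnd_dna(400)
  cA <- paste0(rnd_dna(2000), R, rnd_dna(1500))
  cB <- paste0(rnd_dna(800), R, rnd_dna(700))
  cfg <- genome_config(list(chromosome("a", cA), chromosome("b", cB)))
  rp <- structure(list(id = "Rf", unit1 = interval("a", 2001, 2400),
                       unit2 = interval("b", 801, 1200),
                       orientation = "direct", alignment_length = 400,
                       identity_percent = 100), class = "mito_repeat")
  ev <- enumerate_recombinants(cfg, rp, name = "fused")
  expect_equal(ev$event_class, "fusion")
  expect_equal(config_length(ev$products), nchar(cA) + nchar(cB))
  expect_identical(base_count(config_seqs(ev$products)),
                   base_count(c(cA, cB)))
  # find the two copies in the fusion product and split again
  reps <- find_dispersed_repeats(ev$products, min_length = 300,
                                 min_identity = 99)
  r2 <- as_repeat_pair(reps[reps$orientation == "direct", ][1, ])
  ev2 <- enumerate_recombinants(ev$products, r2, name = "resplit")
  expect_setequal(config_seqs(ev2$products),
                  c(canonical_rotation(chromosome("x", cA))$sequence,
                    canonical_rotation(chromosome("y", cB))$sequence))
})

test_that("inverted repeat inverts the intervening segment; involution", {
  set.seed(102)
  X <- rnd_dna(1500); R <- rnd_dna(500); Y <- rnd_dna(1200); Z <- rnd_dna(1400)
  s <- paste0(X, R, Y, reverse_complement(R), Z)
  cfg <- genome_config(chromosome("c1", s), name = "ref")
  rp <- structure(list(id = "Ri", unit1 = interval("c1", 1501, 2000),
                       unit2 = interval("c1", 3201, 3700, "-"),
                       orientation = "inverted", alignment_length = 500,
                       identity_percent = 100), class = "mito_repeat")
  ev <- enumerate_recombinants(cfg, rp, canonical = FALSE, name = "inv")
  expect_equal(ev$event_class, "inversion")
  p <- ev$products$chromosomes[[1]]
  expect_equal(p$length, nchar(s))
  # duplex pair content conserved (single-strand A/T and C/G swap)
  bc0 <- base_count(s); bc1 <- base_count(p$sequence)
  expect_equal(bc0[1] + bc0[4], bc1[1] + bc1[4])  # A+T
  expect_equal(bc0[2] + bc0[3], bc1[2] + bc1[3])  # C+G
  # inter-repeat segment is reverse-complemented, repeats stay put
  expect_equal(substr(p$sequence, 1501, 2000), R)
  expect_equal(substr(p$sequence, 2001, 3200), reverse_complement(Y))
  # applying the same event again restores the original exactly
  prod <- ev$products
  names(prod$chromosomes) <- prod$chromosomes[[1]]$id <- "c1"
  ev2 <- enumerate_recombinants(prod, rp, canonical = FALSE)
  expect_identical(ev2$products$chromosomes[[1]]$sequence, s)
})

test_that("degenerate repeats are rejected", {
  w <- make_direct_repeat_world(103)
  bad <- w$rp
  bad$unit2 <- interval("c1", 1600, 1900)   # overlaps unit1
  expect_error(enumerate_recombinants(w$ref, bad), "overlap")
  # inverted pair across two circles unsupported
  cfg <- genome_config(list(chromosome("a", rnd_dna(2000)),
                            chromosome("b", rnd_dna(2000))))
  rp <- structure(list(id = "Rx", unit1 = interval("a", 100, 200),
                       unit2 = interval("b", 100, 200, "-"),
                       orientation = "inverted", alignment_length = 101,
                       identity_percent = 100), class = "mito_repeat")
  expect_error(enumerate_recombinants(cfg, rp), "unsupported")
})

test_that("build_junctions splices reference and crossover flanks", {
  w <- make_direct_repeat_world(104)
  X <- w$parts$X; R <- w$parts$R; Y <- w$parts$Y; Z <- w$parts$Z
  tailn <- function(x, n) substr(x, nchar(x) - n + 1, nchar(x))
  headn <- function(x, n) substr(x, 1, n)
  jm <- build_junctions(w$ref, w$rp, flank_length = 200)
  expect_equal(unname(jm$junctions["ref1"]), paste0(tailn(X, 200), R, headn(Y, 200)))
  expect_equal(unname(jm$junctions["ref2"]), paste0(tailn(Y, 200), R, headn(Z, 200)))
  expect_equal(unname(jm$junctions["alt1"]), paste0(tailn(X, 200), R, headn(Z, 200)))
  expect_equal(unname(jm$junctions["alt2"]), paste0(tailn(Y, 200), R, headn(Y, 200)))
  expect_equal(unname(nchar(jm$junctions)), rep(2 * 200 + 300, 4))
  # inverted pair: alt junctions use reverse-complemented partner flanks
  set.seed(104)
  Xi <- rnd_dna(1200); Ri <- rnd_dna(300); Yi <- rnd_dna(900); Zi <- rnd_dna(1100)
  si <- paste0(Xi, Ri, Yi, reverse_complement(Ri), Zi)
  cfgi <- genome_config(chromosome("c1", si))
  rpi <- structure(list(id = "Ri", unit1 = interval("c1", 1201, 1500),
                        unit2 = interval("c1", 2401, 2700, "-"),
                        orientation = "inverted", alignment_length = 300,
                        identity_percent = 100), class = "mito_repeat")
  jmi <- build_junctions(cfgi, rpi, flank_length = 150)
  expect_equal(unname(jmi$junctions["ref1"]),
               paste0(tailn(Xi, 150), Ri, headn(Yi, 150)))
  # unit2 in unit1 orientation: upstream = rc(head of Z), downstream = rc(tail of Y)
  expect_equal(unname(jmi$junctions["ref2"]),
               paste0(reverse_complement(headn(Zi, 150)), Ri,
                      reverse_complement(tailn(Yi, 150))))
  # adjacent units -> duplicated junctions are flagged
  sadj <- paste0(Xi, Ri, Ri, Zi)
  cfga <- genome_config(chromosome("c1", sadj))
  rpa <- structure(list(id = "Ra", unit1 = interval("c1", 1201, 1500),
                        unit2 = interval("c1", 1501, 1800),
                        orientation = "direct", alignment_length = 300,
                        identity_percent = 100), class = "mito_repeat")
  expect_warning(build_junctions(cfga, rpa, flank_length = 100),
                 "adjacent repeat units")
})

test_that("classify_spanning_reads applies anchor, divergence and tie rules", {
  w <- make_direct_repeat_world(105)
  jm <- build_junctions(w$ref, w$rp, flank_length = 200)
  # exact alt1 copy with full flanks
  rs <- classify_spanning_reads(jm$junctions[["alt1"]], jm, min_anchor = 100)
  expect_equal(rs$minor_count, 1)
  expect_equal(unname(rs$per_junction["alt1"]), 1)
  # reverse-complemented read is classified identically
  rs_rc <- classify_spanning_reads(reverse_complement(jm$junctions[["alt1"]]),
                                   jm, min_anchor = 100)
  expect_equal(unname(rs_rc$per_junction["alt1"]), 1)
  # read stopping 50 bp into a flank fails the 100 bp anchor rule
  short <- substr(jm$junctions[["ref1"]], 1, 200 + 300 + 50)
  rs2 <- classify_spanning_reads(short, jm, min_anchor = 100)
  expect_equal(rs2$unassigned, 1)
  expect_equal(rs2$major_count + rs2$minor_count, 0)
  # the same read passes with a 50 bp anchor requirement
  rs3 <- classify_spanning_reads(short, jm, min_anchor = 50)
  expect_equal(rs3$major_count, 1)
  # repeat-only read (no flank anchors) is ambiguous across all junctions
  core <- substr(jm$junctions[["ref1"]], 201, 500)
  rs4 <- classify_spanning_reads(core, jm, min_anchor = 100)
  expect_equal(rs4$unassigned, 1)
  # divergence cap: a heavily corrupted read is unassigned
  set.seed(105)
  rs5 <- classify_spanning_reads(rnd_dna(700), jm, min_anchor = 100)
  expect_equal(rs5$unassigned, 1)
})

test_that("error-free reads from the reference alone yield minor_count 0", {
  w <- make_direct_repeat_world(106)
  spec <- long_read_spec(n_reads = 150, length_mean = 560, length_sd = 20,
                         error_rate = 0, mixture = c(ref = 1),
                         focus = w$focus["ref"], seed = 6)
  rd <- simulate_long_reads(list(ref = w$ref), spec)
  jm <- build_junctions(w$ref, w$rp, flank_length = 200)
  rs <- classify_spanning_reads(rd$reads$seq, jm, min_anchor = 100)
  expect_equal(rs$minor_count, 0)
  expect_equal(rs$major_count, 150)
})

test_that("minor_fraction reproduces published percentages exactly", {
  expect_equal(minor_fraction(17, 7), 29.17)
  expect_equal(minor_fraction(64, 54), 45.76)
  expect_equal(minor_fraction(61, 41), 40.20)
  expect_equal(minor_fraction(10, 0), 0)
  expect_error(minor_fraction(0, 0), "zero")
  expect_error(minor_fraction(-1, 2))
})

test_that("recombination_screen flags only the recombining repeat", {
  w <- make_direct_repeat_world(107)
  # second, non-recombining repeat planted on the same circle
  set.seed(207)
  s <- w$ref$chromosomes$c1$sequence
  R2 <- rnd_dna(300)
  s <- paste0(substr(s, 1, 3600), R2, substr(s, 3901, nchar(s) - 300), R2)
  # rebuild a 2-repeat reference of the same length
  ref2 <- genome_config(chromosome("c1", s), name = "ref")
  reps <- find_dispersed_repeats(ref2, min_length = 250, min_identity = 99)
  expect_equal(nrow(reps), 2)
  # reads: mixture for the recombining pair (units at w$rp coordinates),
  # reference-only elsewhere
  near <- abs(reps$unit1_start - 1501) <= 20
  rp_active <- reps[near, ]
  rp_silent <- reps[!near, ]
  ev <- enumerate_recombinants(ref2, as_repeat_pair(rp_active),
                               canonical = FALSE, name = "mic")
  prods <- lapply(ev$products$chromosomes,
                  function(ch) rotate(ch, ch$length - 1000L))
  alt1 <- genome_config(chromosome("a1", prods[[2]]$sequence), name = "alt1")
  alt2 <- genome_config(chromosome("a2", prods[[1]]$sequence), name = "alt2")
  spec <- long_read_spec(n_reads = 400, length_mean = 560, length_sd = 20,
                         error_rate = 0.05,
                         mixture = c(ref = 0.7, alt1 = 0.15, alt2 = 0.15),
                         focus = list(ref = w$focus$ref,
                                      alt1 = list(chrom = "a1", start = 901,
                                                  end = 1400),
                                      alt2 = list(chrom = "a2", start = 901,
                                                  end = 1400)),
                         seed = 7)
  rd <- simulate_long_reads(list(ref = ref2, alt1 = alt1, alt2 = alt2), spec)
  scr <- recombination_screen(ref2, reps, rd$reads$seq,
                              flank_length = 200, min_anchor = 100)
  tab <- scr$table
  expect_true(tab$supported[tab$repeat_id == rp_active$id])
  expect_false(tab$supported[tab$repeat_id == rp_silent$id])
  # zero reads: nothing flagged
  scr0 <- recombination_screen(ref2, reps, character(0), flank_length = 200)
  expect_false(any(scr0$table$supported))
})
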